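#' Global twisting angle of one subunit
#'
#' The twist is the signed angle spanned by the projections of the EC and
#' TM C-alpha centroids of a subunit on the plane perpendicular to the
#' pseudo-symmetry axis, measured from the TM projection to the EC
#' projection. The sign follows the right-hand rule about the axis
#' (oriented TM -> EC); with this handedness the active-to-resting
#' un-gating transition of the synthetic pentamer is positive.
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()].
#' @param chain subunit chain id.
#' @param af an `axis_frame` (computed from `snap` when omitted).
#' @return signed twist angle in degrees.
#' @export
subunit_twist <- function(snap, topo, chain, af = pore_axis(snap, topo)) {
  ec <- ca_indices(snap, chain, topo$ec_range)
  tm <- ca_indices(snap, chain, topo$tm_range)
  if (!length(ec) || !length(tm)) {
    stop("chain ", chain, ": missing EC or TM C-alpha atoms")
  }
  ec_c <- colMeans(snap$xyz[ec, , drop = FALSE]) - af$origin
  tm_c <- colMeans(snap$xyz[tm, , drop = FALSE]) - af$origin
  signed_angle_about(tm_c, ec_c, af$z, min_norm = 0.1)
}

#' Receptor twisting angle
#'
#' Per-subunit twist angles ([subunit_twist()]) plus their arithmetic
#' mean, the per-snapshot twisting reaction coordinate.
#'
#' @inheritParams subunit_twist
#' @return a list of class `twist_result` with `per_subunit` (named,
#'   degrees) and `mean`.
#' @export
receptor_twist <- function(snap, topo, af = pore_axis(snap, topo)) {
  tau <- vapply(topo$chains, function(ch) {
    tryCatch(subunit_twist(snap, topo, ch, af),
             error = function(e) stop("chain ", ch, ": ", conditionMessage(e)))
  }, numeric(1))
  structure(list(per_subunit = tau, mean = mean(tau)), class = "twist_result")
}

#' @export
print.twist_result <- function(x, ...) {
  cat("twist:", paste(sprintf("%s=%.2f", names(x$per_subunit), x$per_subunit),
                      collapse = " "),
      sprintf("| mean %.2f deg\n", x$mean))
  invisible(x)
}

#' Principal axis of an EC subunit
#'
#' Leading principal component (largest-variance direction) of the EC
#' C-alpha cloud of one subunit, sign-fixed so that it points along the
#' membrane normal (v . Z > 0).
#'
#' @inheritParams subunit_twist
#' @return unit vector of length 3.
#' @export
ec_principal_axis <- function(snap, topo, chain, af = pore_axis(snap, topo)) {
  idx <- ca_indices(snap, chain, topo$ec_range)
  if (length(idx) < 3) stop("chain ", chain, ": need >= 3 EC C-alpha atoms")
  x <- snap$xyz[idx, , drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = 0, nv = 3)
  if (sv$d[1] < 1e-9) {
    stop("degenerate geometry: EC C-alpha cloud of chain ", chain,
         " has no extent")
  }
  v <- sv$v[, 1]
  if (sum(v * af$z) < 0) v <- -v
  if (abs(sum(v * af$z)) < 1e-9) {
    stop("degenerate geometry: EC principal axis of chain ", chain,
         " is perpendicular to the membrane normal")
  }
  v
}

#' Tilt of one EC subunit, decomposed into polar and azimuthal components
#'
#' In the subunit local frame (X radial-outward, Y tangential, Z membrane
#' normal), the polar (radial, "blooming") tilt is the signed angle
#' between Z and the projection of the subunit principal axis v on the XZ
#' plane (positive = outward lean), and the azimuthal (tangential) tilt
#' the signed angle between Z and the projection of v on the YZ plane
#' (positive = lean along +Y). Components whose projection is shorter
#' than 1e-6 are reported as 0.
#'
#' @inheritParams subunit_twist
#' @return named numeric `c(theta_p, theta_a)` in degrees.
#' @export
subunit_tilt <- function(snap, topo, chain, af = pore_axis(snap, topo)) {
  lf <- local_frame(snap, topo, chain, af)
  v <- ec_principal_axis(snap, topo, chain, af)
  a <- sum(v * lf$X); b <- sum(v * lf$Y); cz <- sum(v * lf$Z)
  theta_p <- if (sqrt(a^2 + cz^2) < 1e-6) 0 else atan2(a, cz) * DEG
  theta_a <- if (sqrt(b^2 + cz^2) < 1e-6) 0 else atan2(b, cz) * DEG
  c(theta_p = theta_p, theta_a = theta_a)
}

#' Receptor EC tilt (blooming) angles
#'
#' Per-subunit polar and azimuthal tilt components plus their means.
#'
#' @inheritParams subunit_twist
#' @return a list of class `tilt_result` with matrix `per_subunit`
#'   (rows = subunits, columns theta_p / theta_a) and named `mean`.
#' @export
receptor_tilt <- function(snap, topo, af = pore_axis(snap, topo)) {
  m <- t(vapply(topo$chains, function(ch) subunit_tilt(snap, topo, ch, af),
                numeric(2)))
  structure(list(per_subunit = m, mean = colMeans(m)), class = "tilt_result")
}

#' @export
print.tilt_result <- function(x, ...) {
  cat(sprintf("tilt: mean theta_p %.2f deg, theta_a %.2f deg\n",
              x$mean[["theta_p"]], x$mean[["theta_a"]]))
  invisible(x)
}
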