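#' Pseudo-symmetry axis of the receptor
#'
#' The axis frame anchors every other observable. Its origin is the
#' centroid of all pentamer C-alpha atoms inside the declared EC and TM
#' ranges, and its z axis is the unit vector from the TM C-alpha centroid
#' to the EC C-alpha centroid, i.e. the membrane normal oriented TM -> EC.
#' On a symmetric structure this reduces to the C5 symmetry axis; on real
#' structures it is a robust centroid-based stand-in for it. Residues
#' missing from the model are simply skipped.
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()].
#' @return an object of class `axis_frame` with fields `origin` and `z`.
#' @export
pore_axis <- function(snap, topo) {
  ec <- integer(0); tm <- integer(0)
  for (ch in topo$chains) {
    ec <- c(ec, ca_indices(snap, ch, topo$ec_range))
    tm <- c(tm, ca_indices(snap, ch, topo$tm_range))
  }
  if (!length(ec) || !length(tm)) {
    stop("no C-alpha atoms found in the declared EC/TM ranges")
  }
  ec_c <- colMeans(snap$xyz[ec, , drop = FALSE])
  tm_c <- colMeans(snap$xyz[tm, , drop = FALSE])
  d <- ec_c - tm_c
  if (vnorm(d) < 1e-6) {
    stop("degenerate geometry: EC and TM centroids coincide")
  }
  structure(list(origin = colMeans(snap$xyz[c(ec, tm), , drop = FALSE]),
                 z = unit(d)),
            class = "axis_frame")
}

#' Construct an axis frame directly
#'
#' Useful for synthetic systems whose symmetry axis is known exactly
#' (e.g. the lab z axis of the solvent simulator).
#'
#' @param origin point on the axis (A).
#' @param z axis direction (normalized internally), oriented TM -> EC.
#' @export
axis_frame <- function(origin = c(0, 0, 0), z = c(0, 0, 1)) {
  structure(list(origin = as.numeric(origin), z = unit(as.numeric(z))),
            class = "axis_frame")
}

#' @export
print.axis_frame <- function(x, ...) {
  cat("axis_frame: origin", paste(signif(x$origin, 4), collapse = " "),
      "| z", paste(signif(x$z, 4), collapse = " "), "\n")
  invisible(x)
}

# An arbitrary-but-deterministic orthonormal in-plane basis (e1, e2) for
# the plane perpendicular to af$z. Used for reporting planar coordinates.
plane_basis <- function(af) {
  ref <- if (abs(af$z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * af$z) * af$z)
  list(e1 = e1, e2 = cross3(af$z, e1))
}

# Coordinates of points (n x 3) in the axis frame: columns (u, v, w) with
# w along the axis and (u, v) the in-plane basis from plane_basis().
axis_coords <- function(xyz, af) {
  b <- plane_basis(af)
  rel <- sweep(as.matrix(xyz), 2, af$origin)
  cbind(u = rel %*% b$e1, v = rel %*% b$e2, w = rel %*% af$z)
}

#' Per-subunit local reference frame
#'
#' For one subunit, X is the in-plane unit vector pointing radially
#' outwards from the pseudo-symmetry axis to the EC subunit C-alpha
#' centroid, Z is the axis direction, and Y = Z x X completes the
#' right-handed tangential direction.
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()].
#' @param chain subunit chain id.
#' @param af an `axis_frame` (computed from `snap` when omitted).
#' @return an object of class `local_frame` with unit vectors `X`, `Y`, `Z`.
#' @export
local_frame <- function(snap, topo, chain, af = pore_axis(snap, topo)) {
  idx <- ca_indices(snap, chain, topo$ec_range)
  if (!length(idx)) stop("no EC C-alpha atoms for chain ", chain)
  cen <- colMeans(snap$xyz[idx, , drop = FALSE])
  r <- cen - af$origin
  x_in <- r - sum(r * af$z) * af$z
  if (vnorm(x_in) < 1e-6) {
    stop("degenerate geometry: EC centroid of chain ", chain,
         " lies on the pseudo-symmetry axis")
  }
  X <- unit(x_in)
  structure(list(X = X, Y = cross3(af$z, X), Z = af$z, chain = chain),
            class = "local_frame")
}
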