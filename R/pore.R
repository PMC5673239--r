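#' Default van der Waals radius set for pore profiling
#'
#' Element radii (A) used by the sphere-fit pore profiler: C 1.85, N 1.75,
#' O 1.65, S 2.00, H 1.00 — the classic set used by HOLE-style pore
#' programs. Supply a modified named vector to [pore_radius_profile()] to
#' override.
#'
#' @export
hole_radii <- c(C = 1.85, N = 1.75, O = 1.65, S = 2.00, H = 1.00)

#' C-alpha cross-section of the pore at a prime position
#'
#' The five C-alpha atoms at the given M2 prime position (one per chain)
#' are projected on the plane perpendicular to the pseudo-symmetry axis,
#' ordered by azimuth, and the area of the resulting pentagon is returned
#' (shoelace formula), in nm^2. This is the "ion-pore size" reaction
#' coordinate; for a regular pentagon of circumradius r it equals
#' (5/2) r^2 sin 72 deg.
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()].
#' @param prime M2 prime index (default 9, the constriction in GluCl).
#' @param af an `axis_frame` (computed from `snap` when omitted).
#' @return a list of class `cross_section` with `prime`, `area_nm2` and
#'   `vertices` (the five C-alpha positions, A, in azimuthal order).
#' @export
calpha_cross_section <- function(snap, topo, prime = 9,
                                 af = pore_axis(snap, topo)) {
  resno <- prime_residue(topo, prime)
  idx <- atom_select(snap, chain = topo$chains, resno = resno, elety = "CA")
  if (length(idx) != 5) {
    stop("expected 5 C-alpha atoms at position ", prime, "' (residue ",
         resno, "), found ", length(idx))
  }
  pc <- axis_coords(snap$xyz[idx, , drop = FALSE], af)
  o <- order(atan2(pc[, 2], pc[, 1]))
  area <- shoelace_area(pc[o, 1:2, drop = FALSE])
  structure(list(prime = prime, area_nm2 = area / 100,
                 vertices = snap$xyz[idx[o], , drop = FALSE]),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("cross-section at %s': %.3f nm^2\n", x$prime, x$area_nm2))
  invisible(x)
}

# Largest sphere radius centered in the slice plane at height w:
# maximize over in-plane center c of min_j (||c - x_j|| - r_vdw_j),
# by a deterministic coarse grid plus pattern-search refinement.
.slice_radius <- function(w, uvw, rv, search_radius, coarse_step,
                          refine_tol) {
  cand <- which(sqrt(uvw[, 1]^2 + uvw[, 2]^2) <= 15 & abs(uvw[, 3] - w) <= 15)
  if (!length(cand)) {
    return(c(radius = NA_real_, cu = NA_real_, cv = NA_real_))
  }
  au <- uvw[cand, 1]; av <- uvw[cand, 2]; dz2 <- (uvw[cand, 3] - w)^2
  r <- rv[cand]
  f <- function(cu, cv) {
    # vectorized over centers: rows = centers, cols = atoms
    d <- sqrt(outer(cu, au, function(a, b) (a - b)^2) +
                outer(cv, av, function(a, b) (a - b)^2) +
                rep(dz2, each = length(cu)))
    apply(sweep(d, 2, r), 1, min)
  }
  g <- seq(-search_radius, search_radius, by = coarse_step)
  gg <- expand.grid(cu = g, cv = g)
  gg <- gg[gg$cu^2 + gg$cv^2 <= search_radius^2 + 1e-9, ]
  val <- f(gg$cu, gg$cv)
  refine <- function(cu, cv, fb) {
    step <- coarse_step / 2
    while (step > refine_tol) {
      nu <- cu + step * c(-1, 0, 1, -1, 1, -1, 0, 1)
      nv <- cv + step * c(-1, -1, -1, 0, 0, 1, 1, 1)
      keep <- nu^2 + nv^2 <= search_radius^2 + 1e-9
      if (any(keep)) {
        nval <- f(nu[keep], nv[keep])
        if (max(nval) > fb) {
          k <- which.max(nval)
          cu <- nu[keep][k]; cv <- nv[keep][k]; fb <- max(nval)
          next
        }
      }
      step <- step / 2
    }
    c(fb, cu, cv)
  }
  # pattern-search from the best few coarse cells: the min-of-cones
  # landscape can hold near-tied local maxima
  starts <- utils::head(order(val, decreasing = TRUE), 5)
  res <- vapply(starts, function(i) refine(gg$cu[i], gg$cv[i], val[i]),
                numeric(3))
  best <- which.max(res[1, ])
  c(radius = max(res[1, best], 0), cu = res[2, best], cv = res[3, best])
}

#' Sphere-fit pore radius profile along the channel axis
#'
#' For each slice position z along the pseudo-symmetry axis, finds the
#' largest sphere centered in the slice plane (within `search_radius` of
#' the axis) that touches no atom: radius(z) = max over centers c of
#' min over atoms j of (||c - x_j|| - r_vdw(j)), using full 3D distances.
#' The optimizer is a deterministic coarse grid followed by pattern-search
#' refinement, a reproducible stand-in for simulated-annealing pore
#' tracers; the center is constrained to the slice plane. Slices with no
#' heavy atom within 15 A of the axis are reported as `NA` (undefined, not
#' zero); radii of fully occluded slices are clamped at 0.
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()].
#' @param af an `axis_frame` (computed from `snap` when omitted).
#' @param z_min,z_max axial range in A relative to the axis origin;
#'   defaults to the TM C-alpha extent +/- 5 A.
#' @param step slice spacing in A (default 0.5).
#' @param radii named per-element van der Waals radii (A); must cover all
#'   elements present (hydrogens are excluded from profiling).
#' @param search_radius in-plane search disc radius about the axis (A).
#' @param refine_tol termination step of the pattern search (A).
#' @return a list of class `pore_profile` with `z` (A, axis coordinate),
#'   `radius` (A, `NA` where undefined) and `center` (n x 2 in-plane
#'   optimized center coordinates).
#' @export
pore_radius_profile <- function(snap, topo, af = pore_axis(snap, topo),
                                z_min = NULL, z_max = NULL, step = 0.5,
                                radii = hole_radii, search_radius = 5,
                                refine_tol = 0.02) {
  heavy <- which(snap$atoms$elem != "H")
  if (!length(heavy)) stop("no heavy atoms in snapshot")
  uvw <- axis_coords(snap$xyz[heavy, , drop = FALSE], af)
  elem <- snap$atoms$elem[heavy]
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown)) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  rv <- unname(radii[elem])
  if (is.null(z_min) || is.null(z_max)) {
    tmca <- unlist(lapply(topo$chains, function(ch)
      ca_indices(snap, ch, topo$tm_range)))
    if (!length(tmca)) stop("cannot infer z range: no TM C-alpha atoms")
    wz <- axis_coords(snap$xyz[tmca, , drop = FALSE], af)[, 3]
    if (is.null(z_min)) z_min <- min(wz) - 5
    if (is.null(z_max)) z_max <- max(wz) + 5
  }
  zg <- seq(z_min, z_max, by = step)
  res <- vapply(zg, .slice_radius, numeric(3), uvw = uvw, rv = rv,
                search_radius = search_radius, coarse_step = 0.25,
                refine_tol = refine_tol)
  structure(list(z = zg, radius = unname(res["radius", ]),
                 center = unname(t(res[c("cu", "cv"), , drop = FALSE]))),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  ok <- !is.na(x$radius)
  cat(sprintf("pore profile: %d slices over z [%.1f, %.1f] A, min radius %.2f A\n",
              length(x$z), min(x$z), max(x$z),
              if (any(ok)) min(x$radius[ok]) else NA))
  invisible(x)
}

#' Locate the pore constriction point
#'
#' Global minimum of the radius profile over the TM span; exact ties are
#' resolved by reporting the midpoint of the minimal plateau. The nearest
#' prime position is the prime whose C-alpha ring sits closest in z.
#'
#' @param profile a [pore_radius_profile()].
#' @param topo a [receptor_topology()].
#' @param snap the snapshot the profile was computed from (used for the
#'   prime-ring z positions).
#' @param af the same `axis_frame` used for the profile.
#' @param tm_only restrict the search to the TM C-alpha z extent.
#' @return a list of class `constriction` with `z`, `radius`,
#'   `nearest_prime` and `nearest_residue`.
#' @export
locate_constriction <- function(profile, topo, snap,
                                af = pore_axis(snap, topo), tm_only = TRUE) {
  z <- profile$z; r <- profile$radius
  keep <- !is.na(r)
  if (tm_only) {
    tmca <- unlist(lapply(topo$chains, function(ch)
      ca_indices(snap, ch, topo$tm_range)))
    wz <- axis_coords(snap$xyz[tmca, , drop = FALSE], af)[, 3]
    keep <- keep & z >= min(wz) & z <= max(wz)
  }
  if (!any(keep)) stop("pore profile is empty/undefined over the search span")
  zs <- z[keep]; rs <- r[keep]
  rmin <- min(rs)
  at_min <- which(rs <= rmin + 1e-9)
  # midpoint of the contiguous minimal plateau containing the global min
  runs <- split(at_min, cumsum(c(1, diff(at_min) != 1)))
  first <- which.min(vapply(runs, function(i) rs[i[1]], numeric(1)))
  plate <- runs[[first]]
  z_con <- mean(range(zs[plate]))
  ring_z <- vapply(names(topo$prime_map), function(p) {
    idx <- atom_select(snap, chain = topo$chains,
                       resno = topo$prime_map[[p]], elety = "CA")
    if (!length(idx)) return(NA_real_)
    mean(axis_coords(snap$xyz[idx, , drop = FALSE], af)[, 3])
  }, numeric(1))
  np <- names(which.min(abs(ring_z - z_con)))
  structure(list(z = z_con, radius = rmin, nearest_prime = np,
                 nearest_residue = unname(topo$prime_map[[np]])),
            class = "constriction")
}

#' @export
print.constriction <- function(x, ...) {
  cat(sprintf("constriction: z = %.2f A, radius = %.2f A, nearest prime %s' (residue %d)\n",
              x$z, x$radius, x$nearest_prime, x$nearest_residue))
  invisible(x)
}
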