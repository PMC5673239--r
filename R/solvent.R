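# Default residue names used to select solvent species.
.water_resids <- c("HOH", "TIP3", "TIP", "WAT", "SOL", "SPC")
.ion_resids   <- c("CLA", "SOD", "POT", "CL", "NA", "K", "CL-", "NA+", "K+")

# Indices of the tracked atom of each solvent particle.
.species_indices <- function(atoms, species,
                             water_resids = .water_resids,
                             ion_resids = .ion_resids) {
  switch(species,
    water = which(atoms$resid %in% water_resids & atoms$elem == "O"),
    ion   = which(atoms$resid %in% ion_resids),
    stop("unknown species '", species, "' (use \"water\" or \"ion\")")
  )
}

# Axial position (z) of the 9' constriction point: mean axis-frame z of
# the five 9' C-alpha atoms.
.prime_ring_z <- function(snap, topo, af, prime = 9) {
  resno <- prime_residue(topo, prime)
  idx <- atom_select(snap, chain = topo$chains, resno = resno, elety = "CA")
  if (!length(idx)) stop("no C-alpha atoms at position ", prime, "'")
  mean(axis_coords(snap$xyz[idx, , drop = FALSE], af)[, 3])
}

#' Solvent/ion occupancy of the pore near the constriction point
#'
#' Counts particles of the requested species inside the axial slab
#' |z - z(9')| <= cutoff intersected with the pore cylinder of radius
#' `cylinder_radius` about the pseudo-symmetry axis. The slab-and-cylinder
#' geometry makes the classic occupancy cutoffs (2 A for water oxygens,
#' 5 A for ions) hold the expected handful of particles, which a literal
#' 2 A sphere could not.
#'
#' @param snap a [snapshot()].
#' @param topo a [receptor_topology()].
#' @param af an `axis_frame` (computed from `snap` when omitted).
#' @param species `"water"` (counts oxygens) or `"ion"`.
#' @param cutoff axial half-width of the slab (A); defaults to 2 for
#'   water and 5 for ions.
#' @param cylinder_radius pore-region radius (A, default 6).
#' @param prime prime position defining the constriction (default 9).
#' @return integer count.
#' @export
pore_occupancy <- function(snap, topo, af = pore_axis(snap, topo),
                           species = c("water", "ion"), cutoff = NULL,
                           cylinder_radius = 6, prime = 9) {
  species <- match.arg(species)
  if (is.null(cutoff)) cutoff <- if (species == "water") 2 else 5
  idx <- .species_indices(snap$atoms, species)
  if (!length(idx)) return(0L)
  z9 <- .prime_ring_z(snap, topo, af, prime)
  p <- axis_coords(snap$xyz[idx, , drop = FALSE], af)
  sum(abs(p[, 3] - z9) <= cutoff &
        sqrt(p[, 1]^2 + p[, 2]^2) <= cylinder_radius)
}

#' Count transmembrane permeation events and fluxes
#'
#' A permeation event is the translocation of a particle from one solvent
#' compartment to the other across the membrane. A particle changes
#' compartment state only after fully clearing a `buffer` (default 5 A)
#' hysteresis margin beyond the membrane planes — functionally equivalent
#' to enlarging the periodic box by a buffer layer at top and bottom —
#' and a state change counts as an event only when the path in between
#' includes at least one frame inside the pore cylinder within the
#' membrane slab. Diffusion around the periodic z
#' boundary therefore never counts — the miscount the buffer layer is
#' there to prevent. Upward and downward events are both reported; the
#' flux sums the two.
#'
#' @param traj a [trajectory()] with box information.
#' @param af an `axis_frame`; for solvent boxes the lab frame
#'   (`axis_frame()` at the pore center) is typical.
#' @param species `"water"` or `"ion"`.
#' @param membrane_bounds numeric `c(z_bot, z_top)` membrane slab in
#'   axis-frame z (A). Required.
#' @param buffer hysteresis margin beyond each membrane plane (A).
#' @param cylinder_radius pore cylinder radius for the pore-visit
#'   requirement (A, default 6).
#' @return a list of class `permeation_result`: `events` (data.frame with
#'   particle, direction, entry_frame, exit_frame, time_ps), `flux`
#'   (an [obs_series()] per ns: events_per_ns, cumulative), `total`,
#'   and `per_ns` (total events / trajectory length in ns).
#' @export
count_permeations <- function(traj, af = axis_frame(), species = c("water", "ion"),
                              membrane_bounds, buffer = 5,
                              cylinder_radius = 6) {
  species <- match.arg(species)
  if (is.null(traj$box)) stop("trajectory has no box: cannot unwrap periodic z")
  if (missing(membrane_bounds) || length(membrane_bounds) != 2) {
    stop("membrane_bounds = c(z_bot, z_top) is required")
  }
  zb <- membrane_bounds[1]; zt <- membrane_bounds[2]
  z_mid <- (zb + zt) / 2
  idx <- .species_indices(traj$atoms, species)
  nf <- n_frames(traj)
  if (!length(idx) || nf < 2) {
    return(.permeation_result(data.frame(), traj, nf))
  }
  b <- plane_basis(af)
  np <- length(idx)
  zmat <- matrix(NA_real_, nf, np)
  rmat <- matrix(NA_real_, nf, np)
  for (i in seq_len(nf)) {
    rel <- sweep(matrix(traj$xyz[idx, , i], ncol = 3), 2, af$origin)
    zmat[i, ] <- rel %*% af$z
    rmat[i, ] <- sqrt((rel %*% b$e1)^2 + (rel %*% b$e2)^2)
  }
  in_pore <- rmat <= cylinder_radius &
    abs(zmat - z_mid) <= (zt - zb) / 2
  events <- vector("list", np)
  for (p in seq_len(np)) {
    z <- zmat[, p]
    zone <- ifelse(z > zt + buffer, 1L, ifelse(z < zb - buffer, -1L, 0L))
    def <- which(zone != 0L)
    if (length(def) < 2) next
    st <- zone[def]
    flips <- which(diff(st) != 0L & st[-length(st)] != 0L)
    if (!length(flips)) next
    ev <- list()
    for (k in flips) {
      j <- def[k]; i2 <- def[k + 1]
      span <- j:i2
      if (any(in_pore[span, p])) {
        ev[[length(ev) + 1]] <- data.frame(
          particle = idx[p],
          direction = if (st[k + 1] > st[k]) "up" else "down",
          entry_frame = j, exit_frame = i2,
          time_ps = traj$times[i2])
      }
    }
    if (length(ev)) events[[p]] <- do.call(rbind, ev)
  }
  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events)) events <- data.frame()
  .permeation_result(events, traj, nf)
}

.permeation_result <- function(events, traj, nf) {
  t_ns <- (traj$times[nf] - traj$times[1]) / 1000
  if (t_ns <= 0) t_ns <- NA_real_
  edges <- seq(0, max(traj$times[nf], 1000), by = 1000)
  if (edges[length(edges)] < traj$times[nf]) edges <- c(edges, edges[length(edges)] + 1000)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- if (nrow(events)) {
    as.numeric(table(cut(events$time_ps, edges, include.lowest = TRUE)))
  } else rep(0, length(mids))
  flux <- obs_series(mids,
                     cbind(events_per_ns = counts, cumulative = cumsum(counts)),
                     label = "permeation flux", units = "events/ns")
  structure(list(events = events, flux = flux,
                 total = nrow(events),
                 per_ns = if (is.na(t_ns)) NA_real_ else nrow(events) / t_ns),
            class = "permeation_result")
}

#' @export
print.permeation_result <- function(x, ...) {
  cat(sprintf("permeation: %d events (%.3g per ns)\n", x$total, x$per_ns))
  invisible(x)
}

#' Axial water-density profile inside the pore
#'
#' Histograms water oxygens inside the pore cylinder against the axial
#' coordinate (origin at the 9' ring, or an explicit `z_center`),
#' averaged over frames, and normalizes by the bulk number density
#' measured in the same cylinder outside the membrane region
#' (|z| > membrane half-thickness + `bulk_margin`).
#'
#' @param traj a [trajectory()].
#' @param af an `axis_frame`.
#' @param membrane_bounds `c(z_bot, z_top)` in axis-frame z (A).
#' @param z_center axial origin (A in axis frame); defaults to the
#'   membrane midplane.
#' @param bin bin width (A, default 0.5).
#' @param cylinder_radius pore cylinder radius (A, default 6).
#' @param bulk_margin distance beyond the membrane planes where bulk
#'   starts (A, default 5).
#' @param z_range optional `c(lo, hi)` profile extent relative to
#'   `z_center`; defaults to the data extent.
#' @return a list of class `density_profile`: `z` (bin centers relative
#'   to `z_center`), `density` (O per A^3), `normalized`, `bulk_density`.
#' @export
water_density_profile <- function(traj, af = axis_frame(), membrane_bounds,
                                  z_center = NULL, bin = 0.5,
                                  cylinder_radius = 6, bulk_margin = 5,
                                  z_range = NULL) {
  if (missing(membrane_bounds) || length(membrane_bounds) != 2) {
    stop("membrane_bounds = c(z_bot, z_top) is required")
  }
  idx <- .species_indices(traj$atoms, "water")
  if (!length(idx)) stop("no water oxygens in trajectory")
  nf <- n_frames(traj)
  if (is.null(z_center)) z_center <- mean(membrane_bounds)
  half <- (membrane_bounds[2] - membrane_bounds[1]) / 2
  zs <- c(); rs <- c()
  for (i in seq_len(nf)) {
    p <- axis_coords(matrix(traj$xyz[idx, , i], ncol = 3), af)
    zs <- c(zs, p[, 3] - z_center)
    rs <- c(rs, sqrt(p[, 1]^2 + p[, 2]^2))
  }
  inside <- rs <= cylinder_radius
  if (!any(inside & abs(zs) > half + bulk_margin)) {
    stop("empty bulk region: cannot normalize the profile")
  }
  if (is.null(z_range)) z_range <- range(zs[inside])
  edges <- seq(floor(z_range[1] / bin) * bin,
               ceiling(z_range[2] / bin) * bin, by = bin)
  if (length(edges) < 2) stop("degenerate z range for the density profile")
  h <- graphics::hist(zs[inside & zs >= edges[1] & zs <= edges[length(edges)]],
                      breaks = edges, plot = FALSE)
  vol <- pi * cylinder_radius^2 * bin * nf
  density <- h$counts / vol
  # bulk number density over the bulk bins of the same cylinder (the bulk
  # region is split in two by the membrane; bins handle both sides)
  bulk_mask <- abs(h$mids) > half + bulk_margin
  if (!any(bulk_mask)) stop("empty bulk region: cannot normalize the profile")
  bulk_density <- sum(h$counts[bulk_mask]) / (vol * sum(bulk_mask))
  structure(list(z = h$mids, density = density,
                 normalized = density / bulk_density,
                 bulk_density = bulk_density,
                 membrane_half = half),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("water density profile: %d bins, bulk %.4f O/A^3\n",
              length(x$z), x$bulk_density))
  invisible(x)
}

#' Dehydrated-stretch length of the pore
#'
#' Total and longest contiguous axial extent over which the normalized
#' water density falls below `threshold` (default 1/100 of bulk), within
#' the given span (default: the membrane region of the profile).
#'
#' @param profile a [water_density_profile()] result, or any list with
#'   `z` and `normalized`.
#' @param threshold normalized-density threshold (default 0.01).
#' @param span `c(lo, hi)` axial window (same origin as `profile$z`);
#'   defaults to the membrane span stored in the profile, else the full
#'   profile.
#' @return a list with `total` and `longest` dry lengths (A).
#' @export
dehydrated_stretch <- function(profile, threshold = 0.01, span = NULL) {
  z <- profile$z
  dens <- profile$normalized
  if (is.null(span)) {
    span <- if (!is.null(profile$membrane_half)) {
      c(-profile$membrane_half, profile$membrane_half)
    } else range(z)
  }
  keep <- z >= span[1] & z <= span[2] & !is.na(dens)
  z <- z[keep]; dens <- dens[keep]
  if (!length(z)) return(list(total = 0, longest = 0))
  bin <- if (length(z) > 1) stats::median(diff(z)) else 0
  dry <- dens < threshold
  if (!any(dry)) return(list(total = 0, longest = 0))
  runs <- rle(dry)
  lens <- runs$lengths[runs$values] * bin
  list(total = sum(lens), longest = max(lens))
}
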