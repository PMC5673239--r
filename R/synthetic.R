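#' Parameters of the synthetic C5 pentamer
#'
#' The toy receptor is a pseudo-atom model (C-alpha-only helices and rod
#' subunits plus labeled marker atoms) built for one purpose: providing
#' exact ground truth for every observable in the package. Each subunit
#' has an extracellular (EC) rod of pseudo-C-alpha atoms carrying the
#' binding-site markers on its axis, and a transmembrane (TM) block of
#' four ideal helices (rise 1.5 A, 100 deg per residue, helix radius
#' 2.3 A) whose M2 helix is phased so the 9' C-alpha sits exactly at
#' distance `r9` from the pore axis. Residue numbering mirrors GluCl
#' (9' = 254, M2-M3 proline = 268, beta1-beta2 tip = 45, ...).
#'
#' @param ec_n number of pseudo-C-alpha atoms in the EC rod.
#' @param ec_length rod length (A).
#' @param ec_radius distance of the rod axis from the pore axis (A).
#' @param helix_radius,rise,twist_per_res ideal-helix geometry.
#' @param r9 circumradius of the 9' C-alpha ring (A); 7.67 A gives the
#'   open-state cross-section of 1.40 nm^2.
#' @param p268_r radial position of the M2-M3 proline marker (A).
#' @param delta_z0 baseline vertical beta1-beta2/M2-M3 separation (A).
#' @param sigma Gaussian coordinate noise (A, applied per atom per frame).
#' @param seed RNG seed for the noise.
#' @return a list of class `toy_pentamer_params`.
#' @export
toy_pentamer_params <- function(ec_n = 40, ec_length = 40, ec_radius = 15,
                                helix_radius = 2.3, rise = 1.5,
                                twist_per_res = 100, r9 = 7.67,
                                p268_r = 9.5, delta_z0 = 5,
                                sigma = 0, seed = 1) {
  if (r9 <= helix_radius) {
    stop("geometry error: r9 (", r9, " A) must exceed the helix radius (",
         helix_radius, " A)")
  }
  if (ec_n < 3) stop("EC rod needs at least 3 pseudo-atoms")
  structure(as.list(environment()), class = "toy_pentamer_params")
}

# Toy residue layout (GluCl-like numbering). Helices are 18 residues so
# that the 18 phases (100 deg apart, i.e. all multiples of 20 deg) sum to
# zero and each helix C-alpha centroid falls exactly on its axis: the TM
# subunit centroid then has azimuth exactly at the subunit meridian, which
# makes the imposed twist recover exactly.
.toy_layout <- list(
  ec_range = c(30, 215), tm_range = c(216, 309),
  m1 = c(216, 233), m2 = c(243, 260), m3 = c(270, 287), m4 = c(292, 309),
  rod_res = 60:99,
  p268_z = 28.5,
  markers = data.frame(   # EC markers, placed ON the rod axis line
    resno = c(44, 45, 46, 56, 150, 151, 200, 211),
    resid = c("VAL", "VAL", "GLY", "ARG", "SER", "TYR", "TYR", "ARG"),
    z = c(34, NA, NA, 36, 48, 49, 58, 60),  # V45/G46 depend on delta_z0
    stringsAsFactors = FALSE)
)

.toy_topology <- function() {
  L <- .toy_layout
  receptor_topology(
    chains = LETTERS[1:5],
    ec_range = L$ec_range, tm_range = L$tm_range,
    m_ranges = list(M1 = L$m1, M2 = L$m2, M3 = L$m3, M4 = L$m4),
    prime_map = c("-2" = 243, "2" = 247, "9" = 254, "13" = 258),
    key_residues = c(M2M3_proline = 268, beta12_tip = 45, pore_9prime = 254,
                     orthosteric_plus = 150, orthosteric_minus = 56,
                     allosteric_plus = 281, allosteric_minus = 218,
                     beta_expansion_a = 211, beta_expansion_b = 44,
                     aromatic_1 = 151, aromatic_2 = 200),
    segments = list(m2_sep = c(250, 257), m3_sep = c(274, 281))
  )
}

# Baseline single-chain structure in the local frame (x radial-outward,
# y tangential, z axial), plus bookkeeping indices. All markers and the
# EC rod are collinear along z at x = ec_radius so the EC principal axis
# is exactly (0,0,1) at baseline.
.toy_chain_base <- function(p) {
  L <- .toy_layout
  helix <- function(res, axis_x, axis_y, phase0) {
    k <- seq_along(res) - 1
    th <- (phase0 + p$twist_per_res * k) / DEG
    cbind(axis_x + p$helix_radius * cos(th),
          axis_y + p$helix_radius * sin(th),
          1.5 * 0 + p$rise * k)
  }
  rows <- list(); xyz <- list()
  add <- function(resno, resid, coords) {
    rows[[length(rows) + 1]] <<- data.frame(
      resno = resno, resid = resid, elety = "CA", elem = "C",
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <<- coords
  }
  # TM helices; M2 is phased so residue 254 points exactly inward
  res <- L$m1[1]:L$m1[2]
  add(res, ifelse(res == 218, "LEU", "ALA"), helix(res, 11.5, -4.5, 0))
  res <- L$m2[1]:L$m2[2]
  phase254 <- 180 - p$twist_per_res * (254 - L$m2[1])
  add(res, ifelse(res == 254, "LEU", "ALA"),
      helix(res, p$r9 + p$helix_radius, 0, phase254))
  res <- L$m3[1]:L$m3[2]
  add(res, ifelse(res == 281, "GLY", "ALA"), helix(res, 11.5, 4.5, 0))
  res <- L$m4[1]:L$m4[2]
  add(res, rep("ALA", length(res)), helix(res, 14.5, 0, 0))
  # M2-M3 loop proline marker (TM range, on the meridian plane)
  add(268, "PRO", cbind(p$p268_r, 0, L$p268_z))
  # EC rod
  zrod <- seq(30, 30 + p$ec_length, length.out = p$ec_n)
  add(L$rod_res[seq_len(p$ec_n)], rep("ALA", p$ec_n),
      cbind(p$ec_radius, 0, zrod))
  # EC markers on the rod line; V45 at p268_z + delta_z0, G46 is its
  # counterweight (same line parameter) so the rod principal axis is
  # preserved exactly when V45 is displaced vertically
  mk <- L$markers
  mk$z[mk$resno == 45] <- L$p268_z + p$delta_z0
  mk$z[mk$resno == 46] <- L$p268_z + p$delta_z0
  add(mk$resno, mk$resid, cbind(p$ec_radius, 0, mk$z))
  atoms <- do.call(rbind, rows)
  list(atoms = atoms, xyz = do.call(rbind, xyz))
}

# Apply one conformational state to the baseline chain and place it at
# azimuth phi (degrees). state: list(tau, theta_p, theta_a, r9, delta_z,
# p268_r), all scalars.
.toy_place_chain <- function(base, p, phi, state) {
  L <- .toy_layout
  at <- base$atoms
  xyz <- base$xyz
  ec <- which(at$resno >= L$ec_range[1] & at$resno <= L$ec_range[2])
  m2 <- which(at$resno >= L$m2[1] & at$resno <= L$m2[2])
  i268 <- which(at$resno == 268)
  i45 <- which(at$resno == 45)
  i46 <- which(at$resno == 46)
  # radial M2 displacement realizing the scheduled 9'-ring radius
  xyz[m2, 1] <- xyz[m2, 1] + (state$r9 - p$r9)
  xyz[i268, 1] <- xyz[i268, 1] + (state$p268_r - p$p268_r)
  # EC tilt: rigid rotation about the EC centroid taking z to the target
  # principal-axis direction (local-frame components)
  cen <- colMeans(xyz[ec, , drop = FALSE])
  v <- unit(c(tan(state$theta_p / DEG), tan(state$theta_a / DEG), 1))
  ang <- acos(min(1, max(-1, v[3]))) * DEG
  if (ang > 1e-12) {
    R <- rotation_about(cross3(c(0, 0, 1), v), ang)
    xyz[ec, ] <- sweep(sweep(xyz[ec, , drop = FALSE], 2, cen) %*% t(R),
                       2, cen, `+`)
  }
  # beta1-beta2 placement: slide V45 along the (tilted) rod line until
  # z(V45) = z(P268) + delta_z, with the G46 counterweight slid by the
  # opposite line-parameter increment; both stay on the line, so the EC
  # centroid and principal axis are preserved exactly
  s1 <- sum((xyz[i45, ] - cen) * v)
  s_target <- (xyz[i268, 3] + state$delta_z - cen[3]) / v[3]
  ds <- s_target - s1
  xyz[i45, ] <- cen + (s1 + ds) * v
  s46 <- sum((xyz[i46, ] - cen) * v)
  xyz[i46, ] <- cen + (s46 - ds) * v
  # place at subunit azimuth, then twist the EC block about the pore axis
  Rphi <- rotation_about(c(0, 0, 1), phi)
  xyz <- xyz %*% t(Rphi)
  Rtau <- rotation_about(c(0, 0, 1), state$tau)
  xyz[ec, ] <- xyz[ec, , drop = FALSE] %*% t(Rtau)
  xyz
}

.toy_state <- function(p, tau = 0, theta_p = 0, theta_a = 0, r9 = p$r9,
                       delta_z = p$delta_z0, p268_r = p$p268_r) {
  list(tau = tau, theta_p = theta_p, theta_a = theta_a, r9 = r9,
       delta_z = delta_z, p268_r = p268_r)
}

#' Build the synthetic C5 pentamer
#'
#' Constructs one snapshot of the toy receptor (see
#' [toy_pentamer_params()]) in a chosen conformational state, together
#' with its matching [receptor_topology()]. At `sigma = 0` and default
#' state the structure is exactly C5-symmetric about the lab z axis:
#' twist and both tilt components measure 0, and the 9' cross-section is
#' (5/2) r9^2 sin 72 deg.
#'
#' @param params a [toy_pentamer_params()].
#' @param tau,theta_p,theta_a imposed twist / polar tilt / azimuthal tilt
#'   (degrees, applied identically to the five subunits unless
#'   `tau_offsets` is given).
#' @param r9,delta_z,p268_r imposed 9'-ring radius, beta1-beta2 vertical
#'   separation and proline radial position (A).
#' @param tau_offsets optional numeric(5) per-subunit additive twists.
#' @return list with `snapshot` and `topology`.
#' @export
build_toy_pentamer <- function(params = toy_pentamer_params(), tau = 0,
                               theta_p = 0, theta_a = 0, r9 = params$r9,
                               delta_z = params$delta_z0,
                               p268_r = params$p268_r, tau_offsets = NULL) {
  base <- .toy_chain_base(params)
  chains <- LETTERS[1:5]
  if (is.null(tau_offsets)) tau_offsets <- rep(0, 5)
  atoms <- list(); xyz <- list()
  for (i in 1:5) {
    st <- .toy_state(params, tau = tau + tau_offsets[i], theta_p = theta_p,
                     theta_a = theta_a, r9 = r9, delta_z = delta_z,
                     p268_r = p268_r)
    a <- base$atoms
    a$chain <- chains[i]
    atoms[[i]] <- a[, c("chain", "resno", "resid", "elety", "elem")]
    xyz[[i]] <- .toy_place_chain(base, params, 72 * (i - 1), st)
  }
  xyz <- do.call(rbind, xyz)
  if (params$sigma > 0) {
    xyz <- xyz + with_seed(params$seed,
                           matrix(stats::rnorm(length(xyz), 0, params$sigma),
                                  ncol = 3))
  }
  list(snapshot = snapshot(do.call(rbind, atoms), xyz),
       topology = .toy_topology())
}

#' Un-gating transition schedule
#'
#' Per-frame target values of the quaternary reaction coordinates. The
#' default is the two-step un-gating scenario: a fast global twisting
#' (15.3 -> 21.3 deg, half-transition at 16% of the run) accompanied by
#' azimuthal tilting, pore closing (9'-ring circumradius 7.67 -> 6.95 A,
#' i.e. cross-section 1.40 -> 1.15 nm^2), beta1-beta2 separation growing
#' 5 -> 7 A and the M2-M3 proline moving 4 A inward, followed by the
#' slower radial blooming (7.6 -> 10 deg, half-transition at 50%).
#'
#' @param n_frames number of frames.
#' @param frame_interval frame spacing (ps).
#' @param tau,theta_p,theta_a,r9,delta_z,p268_r `c(from, to)` endpoints.
#' @param tau_mid,theta_p_mid,theta_a_mid,r9_mid,delta_z_mid,p268_r_mid
#'   half-transition times as fractions of the run.
#' @param width logistic width (fraction of the run).
#' @param shape `"logistic"` or `"linear"` (linear ramps ignore the
#'   midpoints).
#' @return a data.frame of class `transition_schedule` with one row per
#'   frame and attribute `times` (ps).
#' @export
transition_schedule <- function(n_frames, frame_interval = 10,
                                tau = c(15.3, 21.3), tau_mid = 0.16,
                                theta_p = c(7.6, 10), theta_p_mid = 0.5,
                                theta_a = c(0, 5), theta_a_mid = 0.16,
                                r9 = c(7.67, 6.95), r9_mid = 0.16,
                                delta_z = c(5, 7), delta_z_mid = 0.16,
                                p268_r = c(9.5, 5.5), p268_r_mid = 0.16,
                                width = 0.05,
                                shape = c("logistic", "linear")) {
  shape <- match.arg(shape)
  f <- (seq_len(n_frames) - 1) / max(n_frames - 1, 1)
  ramp <- function(ends, mid) {
    if (length(ends) == 1) ends <- c(ends, ends)
    if (shape == "linear") ends[1] + (ends[2] - ends[1]) * f
    else ends[1] + (ends[2] - ends[1]) / (1 + exp(-(f - mid) / width))
  }
  out <- data.frame(tau = ramp(tau, tau_mid),
                    theta_p = ramp(theta_p, theta_p_mid),
                    theta_a = ramp(theta_a, theta_a_mid),
                    r9 = ramp(r9, r9_mid),
                    delta_z = ramp(delta_z, delta_z_mid),
                    p268_r = ramp(p268_r, p268_r_mid))
  attr(out, "times") <- frame_interval * (seq_len(n_frames) - 1)
  class(out) <- c("transition_schedule", "data.frame")
  out
}

#' Generate a synthetic un-gating trajectory
#'
#' Applies a [transition_schedule()] to the toy pentamer frame by frame:
#' rigid EC-block twist about the pore axis, per-subunit EC tilts, radial
#' M2 displacement realizing the scheduled 9'-ring radius, vertical
#' beta1-beta2 displacement realizing the scheduled Delta Z, radial
#' proline displacement, then optional Gaussian coordinate noise. At
#' `sigma = 0` every observable recovers its schedule exactly; the same
#' seed always reproduces the same trajectory.
#'
#' @param params a [toy_pentamer_params()] (its `sigma` is overridden by
#'   the `sigma` argument here).
#' @param schedule a [transition_schedule()].
#' @param sigma Gaussian coordinate noise per atom per frame (A).
#' @param seed RNG seed.
#' @param tau_offsets optional numeric(5) constant per-subunit twist
#'   offsets.
#' @return a list with `trajectory`, `topology` and `schedule`.
#' @export
generate_transition <- function(params = toy_pentamer_params(), schedule,
                                sigma = 0, seed = 1, tau_offsets = NULL) {
  stopifnot(inherits(schedule, "transition_schedule"))
  base <- .toy_chain_base(params)
  chains <- LETTERS[1:5]
  if (is.null(tau_offsets)) tau_offsets <- rep(0, 5)
  nf <- nrow(schedule)
  atoms <- list()
  for (i in 1:5) {
    a <- base$atoms
    a$chain <- chains[i]
    atoms[[i]] <- a[, c("chain", "resno", "resid", "elety", "elem")]
  }
  atoms <- do.call(rbind, atoms)
  xyz <- array(NA_real_, c(nrow(atoms), 3, nf))
  for (k in seq_len(nf)) {
    fr <- lapply(1:5, function(i) {
      st <- .toy_state(params, tau = schedule$tau[k] + tau_offsets[i],
                       theta_p = schedule$theta_p[k],
                       theta_a = schedule$theta_a[k],
                       r9 = schedule$r9[k],
                       delta_z = schedule$delta_z[k],
                       p268_r = schedule$p268_r[k])
      .toy_place_chain(base, params, 72 * (i - 1), st)
    })
    xyz[, , k] <- do.call(rbind, fr)
  }
  if (sigma > 0) {
    xyz <- xyz + with_seed(seed, array(stats::rnorm(length(xyz), 0, sigma),
                                       dim = dim(xyz)))
  }
  list(trajectory = trajectory(atoms, xyz, times = attr(schedule, "times")),
       topology = .toy_topology(),
       schedule = schedule)
}

#' Parameters of the solvent permeation simulator
#'
#' A box of non-interacting particles performing a reflected random walk:
#' the membrane slab is impenetrable except inside the pore cylinder, and
#' all box boundaries are periodic. Defaults put the reservoir at liquid
#' water number density (0.0336 particles per A^3) so that an open pore
#' (accessible radius `pore_radius - particle_radius` of 3.8 A) holds
#' about six particles in the canonical 2 A occupancy slab.
#'
#' @param box box lengths (A); the membrane normal is z.
#' @param membrane `c(z_bot, z_top)` slab bounds (A, box coordinates).
#' @param pore_radius pore cylinder radius (A); a scalar or a per-frame
#'   vector (schedule).
#' @param particle_radius hard radius of the particles (A).
#' @param n_water,n_ion particle counts.
#' @param step_sigma random-walk step (A per frame and dimension).
#' @param frame_interval frame spacing (ps).
#' @return a list of class `solvent_sim_params`.
#' @export
solvent_sim_params <- function(box = c(30, 30, 56), membrane = c(18, 38),
                               pore_radius = 5.2, particle_radius = 1.4,
                               n_water = 1090, n_ion = 25,
                               step_sigma = 1.5, frame_interval = 10) {
  if (membrane[1] - 5 < 0 || membrane[2] + 5 > box[3]) {
    stop("box must enclose the membrane slab plus 5 A buffers on both sides")
  }
  if (n_water < 1) stop("need at least one particle")
  structure(as.list(environment()), class = "solvent_sim_params")
}

#' Simulate solvent particles diffusing through a membrane pore
#'
#' Seeded reflected random walk of water-like and ion-like particles (see
#' [solvent_sim_params()]). Rejected moves (into the membrane wall or the
#' pore wall) leave the particle in place, which preserves a uniform
#' stationary distribution over the accessible volume. Returns a
#' [trajectory()] whose atom roster uses standard water/ion residue names
#' so the occupancy, flux and density observables consume it unchanged;
#' the simulation geometry is attached as attribute `sim_params`.
#'
#' @param params a [solvent_sim_params()].
#' @param n_frames number of frames.
#' @param seed RNG seed (the only source of randomness).
#' @return a [trajectory()].
#' @export
simulate_solvent <- function(params = solvent_sim_params(), n_frames = 500,
                             seed = 1) {
  p <- params
  n <- p$n_water + p$n_ion
  r_acc <- pmax(rep(p$pore_radius, length.out = n_frames) - p$particle_radius, 0)
  cx <- p$box[1] / 2; cy <- p$box[2] / 2
  forbidden <- function(pos, racc) {
    inslab <- pos[, 3] > p$membrane[1] & pos[, 3] < p$membrane[2]
    r2 <- (pos[, 1] - cx)^2 + (pos[, 2] - cy)^2
    inslab & (racc <= 0 | r2 > racc^2)
  }
  xyz <- with_seed(seed, {
    pos <- cbind(stats::runif(n, 0, p$box[1]), stats::runif(n, 0, p$box[2]),
                 stats::runif(n, 0, p$box[3]))
    bad <- forbidden(pos, r_acc[1])
    while (any(bad)) {
      k <- sum(bad)
      pos[bad, ] <- cbind(stats::runif(k, 0, p$box[1]),
                          stats::runif(k, 0, p$box[2]),
                          stats::runif(k, 0, p$box[3]))
      bad <- forbidden(pos, r_acc[1])
    }
    out <- array(NA_real_, c(n, 3, n_frames))
    out[, , 1] <- pos
    for (f in 2:n_frames) {
      prop <- pos + matrix(stats::rnorm(3 * n, 0, p$step_sigma), ncol = 3)
      prop <- sweep(prop, 2, p$box, function(x, L) x %% L)
      rej <- forbidden(prop, r_acc[f])
      prop[rej, ] <- pos[rej, ]
      pos <- prop
      out[, , f] <- pos
    }
    out
  })
  atoms <- data.frame(
    chain = rep(c("W", "I"), c(p$n_water, p$n_ion)),
    resno = c(seq_len(p$n_water), seq_len(max(p$n_ion, 0))),
    resid = rep(c("TIP3", "CLA"), c(p$n_water, p$n_ion)),
    elety = rep(c("OH2", "CLA"), c(p$n_water, p$n_ion)),
    elem = rep(c("O", "CL"), c(p$n_water, p$n_ion)),
    stringsAsFactors = FALSE)
  if (p$n_ion == 0) atoms <- atoms[atoms$chain == "W", ]
  traj <- trajectory(atoms, xyz, box = p$box,
                     frame_interval = p$frame_interval)
  attr(traj, "sim_params") <- p
  traj
}
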