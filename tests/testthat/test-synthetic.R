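test_that("toy pentamer defaults are exactly C5 symmetric with known cross-section", {
  tp <- build_toy_pentamer()
  s <- tp$snapshot; topo <- tp$topology
  expect_equal(receptor_twist(s, topo)$mean, 0, tolerance = 1e-9)
  expect_equal(unname(receptor_tilt(s, topo)$mean), c(0, 0), tolerance = 1e-9)
  expect_equal(calpha_cross_section(s, topo, 9)$area_nm2,
               2.5 * 7.67^2 * sin(72 * pi / 180) / 100, tolerance = 1e-9)
  # invalid geometry refused
  expect_error(toy_pentamer_params(r9 = 2), "geometry error")
  # noisy builds are seed-deterministic
  a <- build_toy_pentamer(toy_pentamer_params(sigma = 0.5, seed = 9))$snapshot
  b <- build_toy_pentamer(toy_pentamer_params(sigma = 0.5, seed = 9))$snapshot
  expect_identical(a$xyz, b$xyz)
  c2 <- build_toy_pentamer(toy_pentamer_params(sigma = 0.5, seed = 10))$snapshot
  expect_gt(max(abs(a$xyz - c2$xyz)), 0)
})

test_that("noiseless transitions reproduce every scheduled observable exactly", {
  sched <- transition_schedule(25, tau = c(12, 23), theta_p = c(7.6, 10),
                               theta_a = c(0, 5), r9 = c(7.67, 6.95),
                               delta_z = c(5, 7), shape = "linear")
  run <- generate_transition(schedule = sched, sigma = 0)
  topo <- run$topology
  for (i in c(1, 9, 17, 25)) {
    s <- get_frame(run$trajectory, i)
    af <- pore_axis(s, topo)
    expect_equal(receptor_twist(s, topo, af)$mean, sched$tau[i],
                 tolerance = 1e-6)
    tl <- receptor_tilt(s, topo, af)$mean
    expect_equal(unname(tl), c(sched$theta_p[i], sched$theta_a[i]),
                 tolerance = 1e-6)
    r_meas <- sqrt(calpha_cross_section(s, topo, 9, af)$area_nm2 * 100 /
                     (2.5 * sin(72 * pi / 180)))
    expect_equal(r_meas, sched$r9[i], tolerance = 1e-6)
    expect_equal(delta_z(s, topo, af)$mean, sched$delta_z[i],
                 tolerance = 1e-6)
  }
})

test_that("all-zero schedules give a static trajectory with zero RMSD", {
  sched <- transition_schedule(10, tau = c(0, 0), theta_p = c(0, 0),
                               theta_a = c(0, 0), r9 = c(7.67, 7.67),
                               delta_z = c(5, 5), p268_r = c(9.5, 9.5))
  run <- generate_transition(schedule = sched, sigma = 0)
  ref <- get_frame(run$trajectory, 1)
  sel <- selection_spec(run$topology, "all")
  expect_equal(as.numeric(rmsd_series(run$trajectory, ref, sel)$values),
               rep(0, 10), tolerance = 1e-9)
})

test_that("transitions are recovered from noisy coordinates after smoothing", {
  n <- 250
  sched <- transition_schedule(n, shape = "logistic")
  run <- generate_transition(schedule = sched, sigma = 0.5, seed = 4)
  topo <- run$topology
  tau <- thp <- tha <- dz <- r9m <- numeric(n)
  for (i in seq_len(n)) {
    s <- get_frame(run$trajectory, i)
    af <- pore_axis(s, topo)
    tau[i] <- receptor_twist(s, topo, af)$mean
    tl <- receptor_tilt(s, topo, af)$mean
    thp[i] <- tl[["theta_p"]]; tha[i] <- tl[["theta_a"]]
    dz[i] <- delta_z(s, topo, af)$mean
    r9m[i] <- sqrt(calpha_cross_section(s, topo, 9, af)$area_nm2 * 100 /
                     (2.5 * sin(72 * pi / 180)))
  }
  w <- 25
  smooth <- function(x) as.numeric(block_average(obs_series(seq_len(n), x),
                                                 w)$values)
  rms <- function(x, y) sqrt(mean((x - y)^2))
  expect_lt(rms(smooth(tau), smooth(sched$tau)), 0.5)
  expect_lt(rms(smooth(thp), smooth(sched$theta_p)), 0.5)
  expect_lt(rms(smooth(tha), smooth(sched$theta_a)), 0.5)
  expect_lt(rms(smooth(dz), smooth(sched$delta_z)), 0.2)
  expect_lt(rms(smooth(r9m), smooth(sched$r9)), 0.2)
  # determinism: the same seed reproduces the same trajectory
  run2 <- generate_transition(schedule = sched, sigma = 0.5, seed = 4)
  expect_identical(run$trajectory$xyz, run2$trajectory$xyz)
})

test_that("twist-then-bloom schedules produce the two-step ordering", {
  n <- 200
  sched <- transition_schedule(n)   # twist mid 0.16, bloom mid 0.5
  run <- generate_transition(schedule = sched, sigma = 0.2, seed = 8)
  topo <- run$topology
  tau <- thp <- numeric(n)
  for (i in seq_len(n)) {
    s <- get_frame(run$trajectory, i)
    af <- pore_axis(s, topo)
    tau[i] <- receptor_twist(s, topo, af)$mean
    thp[i] <- receptor_tilt(s, topo, af)$mean[["theta_p"]]
  }
  half_time <- function(x) {
    xs <- stats::filter(x, rep(1 / 9, 9), sides = 2)
    xs <- xs[!is.na(xs)]
    lo <- mean(utils::head(xs, 10)); hi <- mean(utils::tail(xs, 10))
    which(xs > (lo + hi) / 2)[1]
  }
  expect_lt(half_time(tau), half_time(thp))
})

test_that("solvent simulator is seeded, stays out of walls, and respects closure", {
  p <- solvent_sim_params(n_water = 120, n_ion = 5, pore_radius = 5.2)
  t1 <- simulate_solvent(p, n_frames = 40, seed = 2)
  t2 <- simulate_solvent(p, n_frames = 40, seed = 2)
  expect_identical(t1$xyz, t2$xyz)
  t3 <- simulate_solvent(p, n_frames = 40, seed = 3)
  expect_gt(max(abs(t1$xyz - t3$xyz)), 0)
  # no particle inside the membrane wall (outside the accessible cylinder)
  r_acc <- p$pore_radius - p$particle_radius
  for (f in c(1, 20, 40)) {
    s <- get_frame(t1, f)
    z <- s$xyz[, 3]
    r <- sqrt((s$xyz[, 1] - 15)^2 + (s$xyz[, 2] - 15)^2)
    inslab <- z > p$membrane[1] & z < p$membrane[2]
    expect_true(all(r[inslab] <= r_acc + 1e-9))
  }
  # a closed pore (radius below the particle radius) keeps the slab empty
  pc <- solvent_sim_params(n_water = 120, n_ion = 0, pore_radius = 1.0)
  tc <- simulate_solvent(pc, n_frames = 60, seed = 5)
  zall <- tc$xyz[, 3, ]
  expect_false(any(zall > pc$membrane[1] & zall < pc$membrane[2]))
  # box must leave room for the buffer layers
  expect_error(solvent_sim_params(box = c(30, 30, 44), membrane = c(2, 40)),
               "buffer")
})

test_that("expected flux grows with pore radius and vanishes when closed", {
  af <- axis_frame(origin = c(15, 15, 0))
  total_events <- function(radius, seeds) {
    sum(vapply(seeds, function(sd) {
      p <- solvent_sim_params(n_water = 250, n_ion = 0, pore_radius = radius)
      tr <- simulate_solvent(p, n_frames = 400, seed = sd)
      count_permeations(tr, af, "water", membrane_bounds = p$membrane,
                        cylinder_radius = 6)$total
    }, numeric(1)))
  }
  closed <- total_events(1.0, 1)
  mid <- total_events(4.0, 1:3)
  wide <- total_events(6.0, 1:3)
  expect_equal(closed, 0)
  expect_gt(wide, 0)
  expect_lte(mid, wide)
})
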