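test_that("pentagon cross-section matches the closed form and degenerates to 0", {
  tp <- build_toy_pentamer()   # r9 = 7.67 A
  cs <- calpha_cross_section(tp$snapshot, tp$topology, 9)
  expect_equal(cs$area_nm2, 2.5 * 7.67^2 * sin(72 * pi / 180) / 100,
               tolerance = 1e-9)
  expect_equal(cs$area_nm2, 1.399, tolerance = 1e-3)
  expect_equal(nrow(cs$vertices), 5)

  # all five Calpha coincident -> zero area
  s <- tp$snapshot
  idx <- atom_select(s, resno = 254, elety = "CA")
  s$xyz[idx, 1] <- 0; s$xyz[idx, 2] <- 0
  expect_equal(calpha_cross_section(s, tp$topology, 9,
                                    axis_frame())$area_nm2, 0,
               tolerance = 1e-12)

  # fewer than five -> missing-atom error
  keep <- !(s$atoms$resno == 254 & s$atoms$chain == "C")
  s4 <- snapshot(s$atoms[keep, ], s$xyz[keep, ])
  expect_error(calpha_cross_section(s4, tp$topology, 9), "expected 5")
})

test_that("shoelace area equals the fan-triangulation oracle on random pentagons", {
  set.seed(42)
  topo <- build_toy_pentamer()$topology
  worst <- 0
  for (k in 1:1000) {
    xy <- random_convex_pentagon()
    z <- runif(1, -3, 3)
    snap <- make_snap(cbind(xy, z), chain = LETTERS[1:5], resno = 254,
                      resid = "LEU")
    area <- calpha_cross_section(snap, topo, 9, axis_frame())$area_nm2 * 100
    worst <- max(worst, abs(area - fan_area(xy)))
  }
  expect_lt(worst, 1e-9)
})

test_that("cross-section is invariant under rigid motion and chain relabeling", {
  tp <- build_toy_pentamer(tau = 4, theta_p = 2, r9 = 7.1)
  s <- tp$snapshot; topo <- tp$topology
  a0 <- calpha_cross_section(s, topo, 9)$area_nm2
  set.seed(5)
  s2 <- rotate_snapshot(s, random_rotation(), c(3, -7, 12))
  expect_equal(calpha_cross_section(s2, topo, 9)$area_nm2, a0,
               tolerance = 1e-9)
  # cyclic relabeling A->B->C->D->E->A
  s3 <- s
  s3$atoms$chain <- c(B = "A", C = "B", D = "C", E = "D", A = "E")[s3$atoms$chain]
  expect_equal(calpha_cross_section(s3, topo, 9)$area_nm2, a0,
               tolerance = 1e-9)
})

test_that("ring-of-carbons pore radius equals R - r_vdw exactly", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(6 * cos(th), 6 * sin(th), 0)
  snap <- make_snap(ring, resno = 254, chain = rep(LETTERS[1:5], length.out = 12),
                    elety = paste0("C", 1:12))
  topo <- build_toy_pentamer()$topology
  pr <- pore_radius_profile(snap, topo, axis_frame(), z_min = 0, z_max = 0,
                            step = 0.5)
  expect_equal(pr$radius[1], 6 - 1.85, tolerance = 1e-3)
})

test_that("profiler matches the exhaustive-grid oracle on stacked rings and random slices", {
  topo <- build_toy_pentamer()$topology
  # two stacked rings of different radii
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  xyz <- rbind(cbind(6 * cos(th), 6 * sin(th), 0),
               cbind(5 * cos(th), 5 * sin(th), 3))
  snap <- make_snap(xyz, elety = paste0("C", seq_len(nrow(xyz))))
  pr <- pore_radius_profile(snap, topo, axis_frame(), z_min = -1, z_max = 4,
                            step = 0.5)
  for (i in seq_along(pr$z)) {
    expect_equal(pr$radius[i],
                 brute_slice_radius(pr$z[i], xyz, rep("C", nrow(xyz))),
                 tolerance = 0.05)
  }
  # randomized off-center slices
  set.seed(9)
  for (k in 1:50) {
    n <- sample(8:16, 1)
    ang <- runif(n, 0, 2 * pi)
    rad <- runif(n, 3.5, 9)
    xyz <- cbind(rad * cos(ang) + runif(1, -1, 1),
                 rad * sin(ang) + runif(1, -1, 1),
                 runif(n, -2, 2))
    elem <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
    snap <- make_snap(xyz, elety = paste0("X", seq_len(n)), elem = elem)
    pr <- pore_radius_profile(snap, topo, axis_frame(), z_min = 0, z_max = 0)
    expect_equal(pr$radius[1], brute_slice_radius(0, xyz, elem),
                 tolerance = 0.05)
  }
})

test_that("profile radius shrinks when an atom moves toward the center", {
  topo <- build_toy_pentamer()$topology
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  xyz <- cbind(7 * cos(th), 7 * sin(th), 0)
  snap <- make_snap(xyz, elety = paste0("C", 1:8))
  pr0 <- pore_radius_profile(snap, topo, axis_frame(), z_min = 0, z_max = 0)
  cen <- pr0$center[1, ]
  # pull one atom toward the optimized center
  v <- c(cen[1] - xyz[1, 1], cen[2] - xyz[1, 2])
  xyz2 <- xyz
  xyz2[1, 1:2] <- xyz[1, 1:2] + 0.6 * v
  snap2 <- make_snap(xyz2, elety = paste0("C", 1:8))
  pr1 <- pore_radius_profile(snap2, topo, axis_frame(), z_min = 0, z_max = 0)
  expect_lte(pr1$radius[1], pr0$radius[1] + 1e-9)
})

test_that("empty slices are NA, missing radii raise errors", {
  topo <- build_toy_pentamer()$topology
  snap <- make_snap(cbind(c(6, -6), 0, 0), elety = c("C1", "C2"))
  pr <- pore_radius_profile(snap, topo, axis_frame(), z_min = 0, z_max = 40,
                            step = 40)
  expect_false(is.na(pr$radius[1]))
  expect_true(is.na(pr$radius[2]))
  bad <- make_snap(cbind(6, 0, 0), elety = "Q1", elem = "Q")
  expect_error(pore_radius_profile(bad, topo, axis_frame(), z_min = 0,
                                   z_max = 0), "van der Waals")
})

test_that("constriction detection finds minima, plateau midpoints and the 9' ring", {
  topo <- build_toy_pentamer()$topology
  snap <- build_toy_pentamer()$snapshot
  # synthetic profile with a unique minimum at z = 3
  prof <- structure(list(z = seq(0, 10, 0.5),
                         radius = 5 + abs(seq(0, 10, 0.5) - 3),
                         center = NULL), class = "pore_profile")
  con <- locate_constriction(prof, topo, snap, tm_only = FALSE)
  expect_equal(con$z, 3)
  # uniform cylinder -> plateau midpoint
  prof2 <- structure(list(z = seq(0, 10, 0.5),
                          radius = rep(4, 21), center = NULL),
                     class = "pore_profile")
  expect_equal(locate_constriction(prof2, topo, snap, tm_only = FALSE)$z, 5)
  # toy pentamer pinched at the 9' marker
  tp <- build_toy_pentamer(r9 = 6.2)
  pr <- pore_radius_profile(tp$snapshot, tp$topology)
  con <- locate_constriction(pr, tp$topology, tp$snapshot)
  expect_equal(con$nearest_prime, "9")
  expect_equal(con$nearest_residue, 254)
  expect_error(locate_constriction(
    structure(list(z = numeric(0), radius = numeric(0)),
              class = "pore_profile"), topo, snap, tm_only = FALSE),
    "empty")
})
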