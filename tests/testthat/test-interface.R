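test_that("Delta Z measures the vertical beta1-beta2 / M2-M3 separation", {
  tp <- build_toy_pentamer()   # baseline Delta Z = 5 A
  topo <- tp$topology
  expect_equal(delta_z(tp$snapshot, topo)$mean, 5, tolerance = 1e-9)
  s7 <- build_toy_pentamer(delta_z = 7)$snapshot
  expect_equal(delta_z(s7, topo)$mean, 7, tolerance = 1e-9)
  # equal z for proline and tip -> 0
  s0 <- build_toy_pentamer(delta_z = 0)$snapshot
  expect_equal(delta_z(s0, topo)$mean, 0, tolerance = 1e-9)
  # rigid-motion invariance
  set.seed(13)
  s2 <- rotate_snapshot(s7, random_rotation(), c(2, -1, 6))
  expect_equal(delta_z(s2, topo)$mean, 7, tolerance = 1e-9)
})

test_that("Delta Z requires at least four subunits", {
  tp <- build_toy_pentamer()
  drop <- !(tp$snapshot$atoms$resno == 45 &
              tp$snapshot$atoms$chain %in% c("A", "B"))
  s3 <- snapshot(tp$snapshot$atoms[drop, ], tp$snapshot$xyz[drop, ])
  expect_error(delta_z(s3, tp$topology), "at least 4")
})

test_that("proline projection tracks the out -> in loop translocation", {
  tp <- build_toy_pentamer()     # P268 marker at radius 9.5
  s <- tp$snapshot; topo <- tp$topology
  proj <- project_interface_proline(s, s, topo)
  expect_equal(proj$radial, rep(9.5, 5), tolerance = 1e-6)
  # chain A sits at azimuth 0: projected position (9.5, 0)
  expect_equal(c(proj$x[1], proj$y[1]), c(9.5, 0), tolerance = 1e-6)
  # markers moved 4 A inward -> radial distance drops by 4
  s_in <- build_toy_pentamer(p268_r = 5.5)$snapshot
  proj_in <- project_interface_proline(s_in, s, topo)
  expect_equal(proj$radial - proj_in$radial, rep(4, 5), tolerance = 0.1)
  # the TM superposition removes a global rigid motion of the snapshot
  set.seed(17)
  s_moved <- rotate_snapshot(s_in, random_rotation(), c(8, -3, 5))
  proj_m <- project_interface_proline(s_moved, s, topo)
  expect_equal(proj_m$radial, proj_in$radial, tolerance = 1e-6)
  # marker on the axis projects to the pore center
  s_axis <- build_toy_pentamer(p268_r = 1e-9)$snapshot
  proj_0 <- project_interface_proline(s_axis, s, topo)
  expect_equal(proj_0$radial, rep(0, 5), tolerance = 1e-6)
})

test_that("M2-M3 separation equals the centroid-distance oracle", {
  tp <- build_toy_pentamer()
  s <- tp$snapshot; topo <- tp$topology
  sep <- m2_m3_separation(s, topo)
  # brute-force oracle for chain A
  at <- s$atoms
  i2 <- which(at$chain == "A" & at$elety == "CA" & at$resno >= 250 &
                at$resno <= 257)
  i3 <- which(at$chain == "A" & at$elety == "CA" & at$resno >= 274 &
                at$resno <= 281)
  oracle <- sqrt(sum((colMeans(s$xyz[i2, ]) - colMeans(s$xyz[i3, ]))^2))
  expect_equal(unname(sep$per_subunit["A"]), oracle, tolerance = 1e-12)
  # identical selections -> 0
  expect_equal(m2_m3_separation(s, topo, m2_seg = c(250, 257),
                                m3_seg = c(250, 257))$mean, 0)
  # two parallel ideal helices with axes 12.2 A apart
  helix <- function(x0, y0, n = 18) {
    k <- 0:(n - 1); th <- (100 * k) * pi / 180
    cbind(x0 + 2.3 * cos(th), y0 + 2.3 * sin(th), 1.5 * k)
  }
  two <- make_snap(rbind(helix(0, 0), helix(12.2, 0)), resno = c(250:267, 274:291))
  sep2 <- m2_m3_separation(two, topo, m2_seg = c(250, 267),
                           m3_seg = c(274, 291), chains = "A")
  expect_equal(unname(sep2$per_subunit["A"]), 12.2, tolerance = 0.1)
  expect_error(m2_m3_separation(s, topo, m2_seg = c(400, 410),
                                m3_seg = c(274, 281)), "no C-alpha")
})

test_that("binding-site distances follow the (+)/(-) interface pairing", {
  tp <- build_toy_pentamer()
  s <- tp$snapshot; topo <- tp$topology
  orth <- site_distance(s, topo, "orthosteric")
  expect_equal(nrow(orth), 5)
  expect_true(all(orth$distance > 0))
  # crafted two-atom check: distance S150(A+) - R56(B-) by hand
  iA <- atom_select(s, chain = "A", resno = 150, elety = "CA")
  iB <- atom_select(s, chain = "B", resno = 56, elety = "CA")
  d_hand <- sqrt(sum((s$xyz[iA, ] - s$xyz[iB, ])^2))
  expect_equal(orth$distance[orth$principal == "A"], d_hand,
               tolerance = 1e-12)
  allo <- site_distance(s, topo, "allosteric")
  expect_true(all(abs(allo$distance - allo$distance[1]) < 1e-9)) # C5 symmetry
  beta <- site_distance(s, topo, "beta_expansion")
  expect_equal(beta$distance, rep(26, 5), tolerance = 1e-9)  # |z211 - z44| = 60-34
  # cyclic relabeling permutes but preserves the multiset of distances
  s3 <- s
  s3$atoms$chain <- c(B = "A", C = "B", D = "C", E = "D", A = "E")[s3$atoms$chain]
  orth3 <- site_distance(s3, topo, "orthosteric")
  expect_equal(sort(round(orth3$distance, 9)), sort(round(orth$distance, 9)))
})

test_that("neurotransmitter restraint distances are measured from crafted poses", {
  tp <- build_toy_pentamer()
  s <- tp$snapshot; topo <- tp$topology
  # craft one ligand and the receptor-side atoms it is restrained to:
  # Arg56 basic nitrogens on chain B, aromatic rings on chain A
  extra <- data.frame(
    chain = c("B", "B", rep("A", 6), rep("A", 6), "L", "L", "L"),
    resno = c(56, 56, rep(151, 6), rep(200, 6), 900, 900, 900),
    resid = c("ARG", "ARG", rep("TYR", 6), rep("TYR", 6), "LGU", "LGU", "LGU"),
    elety = c("NH1", "NH2", c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
              c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), "OE1", "OE2", "N"),
    elem = c("N", "N", rep("C", 12), "O", "O", "N"),
    stringsAsFactors = FALSE)
  ring1 <- cbind(10 + cos(seq(0, 2 * pi, length.out = 7)[-7]),
                 2 + sin(seq(0, 2 * pi, length.out = 7)[-7]), 45)
  ring2 <- cbind(12 + cos(seq(0, 2 * pi, length.out = 7)[-7]),
                 2 + sin(seq(0, 2 * pi, length.out = 7)[-7]), 47)
  xyz_extra <- rbind(c(5, 5, 40), c(5, 7, 40),
                     ring1, ring2,
                     c(5, 6, 43), c(6, 6, 43), c(11, 2, 46))
  s2 <- snapshot(rbind(s$atoms[, 1:5], extra), rbind(s$xyz, xyz_extra))
  lig <- data.frame(chain = "L", resno = 900)
  d <- site_distance(s2, topo, "lglu_restraints", ligands = lig)
  # salt bridge: min over OE1/OE2 x NH1/NH2 = |(5,6,43)-(5,5,40)| = sqrt(10)
  expect_equal(d$carboxylate_to_arg, sqrt(10), tolerance = 1e-9)
  # cation-pi: |(11,2,46) - mean(ring1, ring2)| = |(0,0,0)| = 0
  expect_equal(d$amine_to_ring, 0, tolerance = 1e-9)
})

test_that("chi rotamer matches crafted geometries and the torsion oracle", {
  topo <- build_toy_pentamer()$topology
  quad_snap <- function(p) {
    make_snap(p, resno = 254, resid = "LEU",
              elety = c("N", "CA", "CB", "CG"), elem = c("N", "C", "C", "C"))
  }
  # anti-periplanar: chi = 180 (trans)
  anti <- quad_snap(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)))
  rot <- chi_rotamer(anti, topo, "A")
  expect_equal(abs(rot$chi), 180, tolerance = 1e-9)
  expect_equal(rot$label, "trans")
  # 60-degree gauche: cis by the |chi| < 90 rule. Bond CA-CB along z,
  # N off at azimuth 0, CG off at azimuth 60.
  gp <- quad_snap(rbind(c(1, 0, -0.5), c(0, 0, 0), c(0, 0, 1),
                        c(cos(pi / 3), sin(pi / 3), 1.5)))
  rot_g <- chi_rotamer(gp, topo, "A")
  expect_equal(rot_g$label, "cis")
  expect_equal(abs(rot_g$chi), 60, tolerance = 1e-6)
  # literal atom ordering is available
  rot_lit <- chi_rotamer(anti, topo, "A", order = "literal")
  expect_true(is.finite(rot_lit$chi))
  # oracle check on 100 random quadruples against bio3d's torsion
  set.seed(31)
  for (k in 1:100) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    # skip near-degenerate chains
    if (min(dist(p)) < 0.5) next
    snapq <- quad_snap(p)
    chi <- chi_rotamer(snapq, topo, "A")$chi
    oracle <- bio3d::torsion.xyz(as.numeric(t(p)), atm.inc = 4)
    expect_equal(((chi - oracle + 180) %% 360) - 180, 0, tolerance = 1e-6)
  }
  # missing side-chain atom errors
  incomplete <- make_snap(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)),
                          resno = 254, elety = c("N", "CA", "CB"))
  expect_error(chi_rotamer(incomplete, topo, "A"), "missing")
})

test_that("interface geometry correlates with the imposed un-gating schedule", {
  sched <- transition_schedule(60, shape = "logistic")
  run <- generate_transition(schedule = sched, sigma = 0)
  topo <- run$topology
  nf <- n_frames(run$trajectory)
  dz <- tau <- xs <- numeric(nf)
  for (i in seq_len(nf)) {
    s <- get_frame(run$trajectory, i)
    af <- pore_axis(s, topo)
    dz[i] <- delta_z(s, topo, af)$mean
    tau[i] <- receptor_twist(s, topo, af)$mean
    xs[i] <- calpha_cross_section(s, topo, 9, af)$area_nm2
  }
  expect_gt(pearson(dz, tau), 0.9)
  expect_lt(pearson(dz, xs), -0.9)
})
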