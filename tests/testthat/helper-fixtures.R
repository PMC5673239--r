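# Shared fixtures and independent oracles, all built in code.

# Minimal snapshot from a coordinate matrix of pseudo-atoms.
make_snap <- function(xyz, chain = "A", resno = NULL, resid = "ALA",
                      elety = "CA", elem = "C", box = NULL, time = 0) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  snapshot(data.frame(chain = rep_len(chain, n), resno = resno,
                      resid = rep_len(resid, n), elety = rep_len(elety, n),
                      elem = rep_len(elem, n), stringsAsFactors = FALSE),
           xyz, box = box, time = time)
}

# Rodrigues rotation matrix (degrees) - test-side twin of the package's
# internal helper so tests only touch the public surface.
rot_about <- function(axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  th <- theta * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_snapshot <- function(snap, R, shift = c(0, 0, 0)) {
  snap$xyz <- sweep(snap$xyz %*% t(R), 2, shift, `+`)
  snap
}

# Independent polygon-area oracle: fan triangulation from an interior
# point using explicit triangle cross products. The default center (the
# origin) is interior for polygons built star-shaped about the origin.
fan_area <- function(xy, c0 = c(0, 0)) {
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    a <- xy[i, ] - c0
    b <- xy[if (i == n) 1 else i + 1, ] - c0
    s <- s + abs(a[1] * b[2] - a[2] * b[1]) / 2
  }
  s
}

# Random convex pentagon containing the origin: five sorted parameter
# angles on a randomly oriented ellipse whose center stays close enough
# to the origin that the origin remains interior (as the pore axis is
# interior to the 9' ring).
random_convex_pentagon <- function() {
  a <- runif(1, 4, 10); b <- runif(1, 4, 10)
  # one vertex per 72-degree sector keeps the pentagon wrapped around
  # the center instead of collapsing into a sliver
  t <- 2 * pi * (0:4) / 5 + runif(5, 0.02, 2 * pi / 5 - 0.02)
  pts <- cbind(a * cos(t), b * sin(t))
  rot <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  off <- runif(2, -0.15, 0.15) * min(a, b)
  sweep(pts %*% R, 2, off, `+`)
}

# Exhaustive-grid oracle for the slice sphere radius: max over a 0.05 A
# center grid (disc of radius 5) of min_j (3D distance - vdw).
brute_slice_radius <- function(z, xyz, elem, radii = hole_radii,
                               grid = 0.05, search_radius = 5) {
  g <- seq(-search_radius, search_radius, by = grid)
  gg <- expand.grid(u = g, v = g)
  gg <- gg[gg$u^2 + gg$v^2 <= search_radius^2 + 1e-12, ]
  rv <- radii[elem]
  d2z <- (z - xyz[, 3])^2
  d <- sqrt(outer(gg$u, xyz[, 1], `-`)^2 + outer(gg$v, xyz[, 2], `-`)^2 +
              rep(d2z, each = nrow(gg))) - rep(rv, each = nrow(gg))
  max(max(apply(d, 1, min)), 0)
}

# Seeded AR(1) series with autocorrelation time tau (in units of dt).
ar1_series <- function(n, tau, dt = 1, seed = 1) {
  phi <- exp(-dt / tau)
  set.seed(seed)
  x <- numeric(n)
  for (i in 2:n) x[i] <- phi * x[i - 1] + rnorm(1)
  x
}

# Crafted single-particle solvent trajectory from a z path (xy fixed).
path_trajectory <- function(z, xy = c(10, 10), box = c(20, 20, 60),
                            chain = "W", resid = "TIP3", elety = "OH2",
                            elem = "O") {
  atoms <- data.frame(chain = chain, resno = 1, resid = resid,
                      elety = elety, elem = elem, stringsAsFactors = FALSE)
  xyz <- array(NA_real_, c(1, 3, length(z)))
  xyz[1, 1, ] <- xy[1]; xyz[1, 2, ] <- xy[2]; xyz[1, 3, ] <- z
  trajectory(atoms, xyz, box = box, frame_interval = 10)
}

# Multi-particle version: z is a frames x particles matrix.
paths_trajectory <- function(zmat, xy = c(10, 10), box = c(20, 20, 60)) {
  np <- ncol(zmat)
  atoms <- data.frame(chain = "W", resno = seq_len(np), resid = "TIP3",
                      elety = "OH2", elem = "O", stringsAsFactors = FALSE)
  xyz <- array(NA_real_, c(np, 3, nrow(zmat)))
  xyz[, 1, ] <- xy[1]; xyz[, 2, ] <- xy[2]
  for (f in seq_len(nrow(zmat))) xyz[, 3, f] <- zmat[f, ]
  trajectory(atoms, xyz, box = box, frame_interval = 10)
}

# 3-atom PDB text fixture.
write_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.200   3.300   3.000  1.00  0.00           C",
    "END"), path)
  path
}
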