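# Small geometry helpers shared across observables. All lengths in Angstrom,
# all angles in degrees unless a name says otherwise.

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) stop("degenerate geometry: cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `theta` degrees about the (not necessarily unit)
#' vector `axis`, right-handed.
#'
#' @param axis numeric length-3 axis vector.
#' @param theta rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @keywords internal
rotation_about <- function(axis, theta) {
  k <- unit(axis)
  th <- theta / DEG
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Signed angle (degrees) from vector a to vector b about unit axis z,
# a and b being projected implicitly onto the plane perpendicular to z.
signed_angle_about <- function(a, b, z, min_norm = 0) {
  ap <- a - sum(a * z) * z
  bp <- b - sum(b * z) * z
  if (vnorm(ap) <= min_norm || vnorm(bp) <= min_norm) {
    stop("degenerate geometry: projection onto the plane is too short")
  }
  atan2(sum(cross3(ap, bp) * z), sum(ap * bp)) * DEG
}

# Dihedral angle (degrees, in (-180, 180]) over the ordered points p1..p4.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  # IUPAC sign convention (matches standard structural-biology torsions)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps all generator randomness explicit.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Shoelace area of a planar polygon given as an n x 2 matrix of vertices.
shoelace_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
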