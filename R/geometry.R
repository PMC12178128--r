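# Low-level 3D geometry shared by the structure, feature and synthetic modules.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-10) stop("degenerate zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Signed dihedral angle of four points
#'
#' Returns the torsion angle p1-p2-p3-p4 in radians in (-pi, pi], using the
#' IUPAC sign convention (clockwise positive looking from p2 to p3).
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in radians.
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

bond_angle <- function(p1, p2, p3) {
  v1 <- unit(p1 - p2)
  v2 <- unit(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2))))
}

#' Place a fourth atom from internal coordinates (NeRF)
#'
#' Given three already-placed atoms `a`, `b`, `c`, returns the position `d`
#' with bond length |c-d| = `bond`, bond angle b-c-d = `angle`, and torsion
#' a-b-c-d = `torsion`. Inverse of [dihedral_angle()]:
#' `dihedral_angle(a, b, c, place_atom(a, b, c, ...)) == torsion`.
#'
#' @param a,b,c Numeric length-3 positions.
#' @param bond Bond length (Angstrom), > 0.
#' @param angle Bond angle (radians).
#' @param torsion Dihedral angle (radians).
#' @return Numeric length-3 position.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          -bond * sin(angle) * sin(torsion))
  as.numeric(c + m %*% d2)
}

# Apply rigid transform x -> x R^T + t to an n x 3 matrix.
apply_rigid <- function(coords, rotation, translation) {
  coords %*% t(rotation) + matrix(translation, nrow(coords), 3L, byrow = TRUE)
}

# Pairwise Euclidean distance matrix of an n x 3 coordinate matrix.
pairwise_dist <- function(coords) {
  as.matrix(stats::dist(coords))
}

# Evaluate an expression with a private, restored RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Stable integer hash for deriving sub-seeds; documented so ladders are
# reproducible independent of generation order. Stays below 2^31.
stable_hash <- function(...) {
  parts <- as.numeric(c(...))
  m <- 2147483647
  h <- 17
  for (p in parts) h <- (h * 1000003 + (p %% m)) %% m
  as.integer(h)
}
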