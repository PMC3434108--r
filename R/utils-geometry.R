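# Internal geometric and numeric helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Angle A-B-C in degrees.
angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  rad2deg(acos(max(-1, min(1, cosang))))
}

## Torsion angle A-B-C-D in degrees, in (-180, 180].
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

## Place atom D given positions A, B, C, the C-D bond length, the B-C-D
## angle (deg) and the A-B-C-D torsion (deg).  Standard internal-coordinate
## (NeRF-style) construction used by the synthetic builders.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d2 + c)
}

## Pairwise Euclidean distances between the rows of two coordinate matrices.
cross_dist <- function(x, y) {
  x2 <- rowSums(x * x)
  y2 <- rowSums(y * y)
  d2 <- outer(x2, y2, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Rounding half away from zero (R's round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random state.  All synthetic generators route their randomness here so a
## seed travels with every spec rather than living in global state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
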