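# Internal 3-D geometry helpers shared by the structural operators and the
# synthetic fixture builders.  All angles are in degrees.

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vunit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector", call. = FALSE)
  v / n
}

#' Angle defined by three points
#'
#' @param p1,p2,p3 Numeric xyz coordinates; the angle is at `p2`.
#' @return Angle in degrees in \[0, 180\].
#' @export
angle_points <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral angle defined by four points
#'
#' Torsion of `p4` about the `p2`-`p3` axis relative to `p1`, using the
#' IUPAC sign convention.
#'
#' @param p1,p2,p3,p4 Numeric xyz coordinates.
#' @return Angle in degrees in (-180, 180\].
#' @export
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# NeRF atom placement: position X such that |r3-X| = dist,
# angle(r2, r3, X) = angle and torsion(r1, r2, r3, X) = torsion.
place_atom <- function(r1, r2, r3, dist, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(r3 - r2)
  n <- vunit(vcross(r2 - r1, bc))
  m <- vcross(n, bc)
  d <- c(-dist * cos(ang),
         dist * sin(ang) * cos(tor),
         -dist * sin(ang) * sin(tor))
  r3 + d[1L] * bc + d[2L] * m + d[3L] * n
}

# Ideal CB reconstruction for an L-amino acid from backbone N, CA, C
# (standard tetrahedral-frame coefficients, bond length 1.522 A).
ideal_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- vcross(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

# apply a rigid rotation + translation to a structure model (used in
# invariance tests and exported for convenience)

#' Rigidly transform a structure model
#'
#' Applies `x -> R x + t` to every atom coordinate.  Useful for checking
#' that geometric detectors are frame-independent.
#'
#' @param model A `structure_model`.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param translation Length-3 numeric vector (default zero).
#' @return The transformed `structure_model`.
#' @export
transform_structure <- function(model, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  new <- xyz %*% t(rotation)
  new <- sweep(new, 2L, translation, `+`)
  model$atoms$x <- new[, 1L]
  model$atoms$y <- new[, 2L]
  model$atoms$z <- new[, 3L]
  model
}
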