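# Small 3D geometry kernel shared by the lid-frame, restraint and
# disulfide-design code.  Angles in degrees, distances in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle defined by three points
#'
#' @param a,b,c Numeric 3-vectors; the angle is at `b`.
#' @return Angle a-b-c in degrees, in (0, 180).
#' @export
angle_deg <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral (torsion) angle defined by four points
#'
#' Signed torsion a-b-c-d using the IUPAC convention: looking down b->c,
#' positive is clockwise rotation of d relative to a.
#'
#' @param a,b,c,d Numeric 3-vectors.
#' @return Torsion in degrees, in (-180, 180].
#' @export
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF) construction: given three placed atoms a-b-c,
#' returns the position d with bond length |c-d|, angle b-c-d and torsion
#' a-b-c-d as requested.
#'
#' @param a,b,c Numeric 3-vectors of previously placed atoms.
#' @param bond Bond length c-d in Angstrom.
#' @param angle Angle b-c-d in degrees.
#' @param dihedral Torsion a-b-c-d in degrees.
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix about a unit axis by theta radians (Rodrigues).
rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Circular distance between two angles in degrees, result in [0, 180].
circular_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
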