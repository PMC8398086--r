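## Small 3D geometry kernel shared by the structure modules.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

#' Signed dihedral angle of four points
#'
#' Standard right-hand (IUPAC) torsion convention: looking from `p2` to
#' `p3`, the angle is positive when `p4` is rotated clockwise relative to
#' `p1`. Returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric(3) coordinates, Angstrom.
#' @return angle in degrees.
#' @examples
#' dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))  # cis: 0
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("undefined dihedral: three consecutive points are collinear")
  m1 <- .cross3(n1, .unit(b2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## internal-to-Cartesian (NeRF) placement: position of atom D bonded to C,
## given bond length r(C-D), angle theta(B-C-D) and torsion phi(A-B-C-D),
## both in degrees, with the sign convention of dihedralAngle().
.place_atom <- function(a, b, c_, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- .unit(c_ - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c_ + d[1] * bc + d[2] * m + d[3] * n
}

## Euler rotation matrix: successive rotations about x, then y, then z axes
.euler_matrix <- function(angles) {
  a <- angles * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

.coords <- function(structure) {
  as.matrix(structure@atoms[, c("x", "y", "z")])
}

.set_coords <- function(structure, xyz) {
  structure@atoms$x <- xyz[, 1]
  structure@atoms$y <- xyz[, 2]
  structure@atoms$z <- xyz[, 3]
  structure
}
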