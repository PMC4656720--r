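#' @name geometry
#' @title Rotation and spherical-coordinate helpers
#' @description Elementary right-handed rotation matrices, their angle
#'   derivatives, and the shoulder-centered spherical convention used across
#'   the simulator: azimuth `theta` = atan2(y, x) in `[0, pi]` (objects sit in
#'   the y > 0 hemispace), elevation `phi` = -acos(z / rho) in `[-pi, 0]`
#'   (so `phi = -pi/2` is the horizontal plane), radius `rho` in meters.
NULL

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0,  0, c, s,  0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s,  0, 1, 0,  s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0,  -s, c, 0,  0, 0, 1), 3, 3)
}
# angle derivatives d/da R(a)
drot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(0, 0, 0,  0, -s, c,  0, -c, -s), 3, 3)
}
drot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(-s, 0, -c,  0, 0, 0,  c, 0, -s), 3, 3)
}
drot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(-s, c, 0,  -c, -s, 0,  0, 0, 0), 3, 3)
}

# intrinsic z-y-x Euler rotation used for object orientation (o_x, o_y, o_z)
euler_matrix <- function(o) rot_z(o[3]) %*% rot_y(o[2]) %*% rot_x(o[1])

#' Convert a shoulder-centered Cartesian point to spherical pose
#' @param p numeric 3-vector (m).
#' @return c(theta = azimuth, phi = elevation, rho = radius).
#' @export
cart_to_sph <- function(p) {
  rho <- sqrt(sum(p^2))
  if (rho < 1e-12) return(c(theta = 0, phi = -pi / 2, rho = 0))
  theta <- atan2(p[2], p[1])
  phi <- -acos(pmin(1, pmax(-1, p[3] / rho)))
  c(theta = theta, phi = phi, rho = rho)
}

#' Convert a shoulder-centered spherical pose to Cartesian
#' @param theta azimuth (rad), `phi` elevation (rad, in `[-pi, 0]`),
#'   `rho` radius (m).
#' @param phi,rho see `theta`.
#' @return numeric 3-vector.
#' @export
sph_to_cart <- function(theta, phi, rho) {
  polar <- -phi
  rho * c(sin(polar) * cos(theta), sin(polar) * sin(theta), cos(polar))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) v else v / n
}
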