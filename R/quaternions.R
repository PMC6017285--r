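## Quaternion and rotation helpers.
##
## Quaternions are length-4 numeric vectors c(w, x, y, z) with |q| = 1,
## and represent the rotation taking body-frame vectors to the lab frame.
## Euler angles follow the intrinsic Z-Y'-Z'' convention: R = Rz(alpha)
## Ry(beta) Rz(gamma).

#' Convert Euler angles to a unit quaternion
#'
#' Angles follow the intrinsic Z-Y'-Z'' convention (rotation matrix
#' `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`), the standard parameterization for
#' rigid-body orientations of a guest relative to a host-fixed frame.
#'
#' @param alpha,beta,gamma Euler angles in radians.
#' @return A unit quaternion as a numeric vector `c(w, x, y, z)`.
#' @export
#' @examples
#' euler_to_quaternion(0, 0, 0)            # identity
#' euler_to_quaternion(pi / 2, pi / 4, 0)
euler_to_quaternion <- function(alpha, beta, gamma) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma))
  qz1 <- c(cos(alpha / 2), 0, 0, sin(alpha / 2))
  qy <- c(cos(beta / 2), 0, sin(beta / 2), 0)
  qz2 <- c(cos(gamma / 2), 0, 0, sin(gamma / 2))
  q <- quat_multiply(quat_multiply(qz1, qy), qz2)
  q / sqrt(sum(q^2))
}

#' Quaternion product
#'
#' Hamilton product `a %*% b`; composing rotations so that
#' `quaternion_to_matrix(quat_multiply(a, b))` equals
#' `quaternion_to_matrix(a) %*% quaternion_to_matrix(b)`.
#'
#' @param a,b Quaternions `c(w, x, y, z)`.
#' @return The product quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Rotation matrix of a unit quaternion
#'
#' @param q Unit quaternion `c(w, x, y, z)`.
#' @return A 3x3 rotation matrix mapping body-frame vectors to the lab frame.
#' @export
quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from an axis-angle rotation vector
#'
#' `v` is an axis-angle rotation vector whose norm is the rotation angle in
#' radians.  Used to advance orientations from an angular velocity over a
#' time step.
#'
#' @param v Numeric length-3 rotation vector (radians).
#' @return A unit quaternion.
#' @export
quat_from_rotvec <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-300) {
    return(c(1, 0, 0, 0))
  }
  axis <- v / theta
  c(cos(theta / 2), sin(theta / 2) * axis)
}

#' Uniform random unit quaternions
#'
#' Shoemake's subgroup algorithm: exactly uniform over the rotation group.
#'
#' @param n Number of quaternions.
#' @return An `n x 4` matrix of unit quaternions, one per row.
#' @export
random_quaternions <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )
}

## Rotate an n x 3 coordinate matrix by quaternion q (body -> lab).
rotate_coords <- function(xyz, q) {
  xyz %*% t(quaternion_to_matrix(q))
}
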