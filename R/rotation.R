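# Rotation utilities shared across the package. All rotations are 3x3 proper
# orthonormal matrices; the axis-angle (rotation vector) form is used for
# local parametrization in the optimizers.

#' Rotation matrix from an axis-angle vector
#'
#' Rodrigues' formula. The rotation vector's direction is the axis and its
#' norm the angle in radians; the zero vector maps to the identity.
#'
#' @param w numeric length-3 rotation vector.
#' @return 3x3 rotation matrix.
#' @export
rot_from_rotvec <- function(w) {
  th <- vnorm(w)
  if (th < 1e-12) {
    W <- skew3(w)
    return(diag(3) + W + 0.5 * W %*% W)
  }
  k <- w / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Axis-angle vector from a rotation matrix
#'
#' Inverse of [rot_from_rotvec()]; returns the minimal rotation vector
#' (angle in \[0, pi\]).
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 rotation vector.
#' @export
rotvec_from_rot <- function(R) {
  ct <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  th <- acos(ct)
  if (th < 1e-10) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (th > pi - 1e-6) {
    # near pi: axis from the symmetric part
    A <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(A), 0))
    # fix signs from off-diagonals
    i <- which.max(axis)
    if (i == 1) axis <- c(axis[1], A[1, 2] / axis[1], A[1, 3] / axis[1])
    if (i == 2) axis <- c(A[1, 2] / axis[2], axis[2], A[2, 3] / axis[2])
    if (i == 3) axis <- c(A[1, 3] / axis[3], A[2, 3] / axis[3], axis[3])
    return(unit(axis) * th)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  axis * th
}

#' Geodesic angle between two rotations
#'
#' @param Ra,Rb 3x3 rotation matrices.
#' @return angle in radians in \[0, pi\].
#' @export
rotation_angle <- function(Ra, Rb = diag(3)) {
  Rrel <- Ra %*% t(Rb)
  ct <- max(-1, min(1, (sum(diag(Rrel)) - 1) / 2))
  acos(ct)
}

# Project a near-rotation onto SO(3) via SVD (used after accumulating
# numerical error, never as part of an estimator).
closest_rotation <- function(M) {
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  R
}

# Uniform random rotation (Arvo / quaternion method), uses the current RNG.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
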