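#' Rigid camera pose (world-to-camera)
#'
#' The pose maps world points into the camera frame: `x_cam = R %*% X + t`.
#' The camera center in world coordinates is `-t(R) %*% t`.
#'
#' @param R 3x3 proper orthonormal rotation (world-to-camera).
#' @param t length-3 translation in meters (world-to-camera).
#' @return an object of class `camera_pose`.
#' @export
camera_pose <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
    stop("R must be a proper orthonormal rotation")
  obj <- list(R = R, t = as.numeric(t))
  class(obj) <- "camera_pose"
  obj
}

#' @export
print.camera_pose <- function(x, ...) {
  cc <- pose_center(x)
  cat(sprintf("camera_pose (world-to-camera): center (%.4g, %.4g, %.4g), angle %.4g deg\n",
              cc[1], cc[2], cc[3], rotation_angle(x$R) * 180 / pi))
  invisible(x)
}

#' Camera center in world coordinates
#' @param P a [camera_pose()].
#' @return length-3 numeric vector.
#' @export
pose_center <- function(P) as.numeric(-crossprod(P$R, P$t))

# Compose: pose of frame transform Pb after Pa? Here: world->cam map of
# (Pa o Pb^-1) is not needed; we only need relative pose: x_b = R_rel x_a + t_rel
relative_pose <- function(Pa, Pb) {
  # maps camera-a coordinates to camera-b coordinates
  R <- Pb$R %*% t(Pa$R)
  t <- Pb$t - R %*% Pa$t
  camera_pose(R, as.numeric(t))
}

# Apply a Sim(3) to a pose expressed in the source world frame, returning the
# pose in the target world frame. If world transforms as Y = s R_s X + t_s,
# then x_cam = R X + t = R R_s^T (Y - t_s)/s + t, i.e.
# R' = R R_s^T, t' = t - R' t_s / s ... with the metric scale folded into t.
transform_pose_sim3 <- function(P, S) {
  Rn <- P$R %*% t(S$R)
  tn <- S$s * P$t - Rn %*% S$t
  camera_pose(Rn, as.numeric(tn))
}

#' Look-at camera pose
#'
#' Builds a world-to-camera pose for a camera at `center` whose optical axis
#' (+z in the camera frame) points at `target`. The camera is rolled so that
#' the world up direction maps to image up (image y axis points down), the
#' convention used by the synthetic rig.
#'
#' @param center,target length-3 world points in meters.
#' @param up world up direction (default +z).
#' @return a [camera_pose()].
#' @export
look_at_pose <- function(center, target, up = c(0, 0, 1)) {
  z <- unit(target - center)
  upo <- up - sum(up * z) * z
  if (vnorm(upo) < 1e-9) {
    # viewing straight along up: fall back to world x as the up hint
    upo <- c(1, 0, 0) - sum(c(1, 0, 0) * z) * z
  }
  ycam <- -unit(upo)           # image y points down
  xcam <- cross3(ycam, z)      # right-handed: x = y x z
  R <- rbind(xcam, ycam, z, deparse.level = 0)
  camera_pose(R, as.numeric(-R %*% center))
}

#' Project a world point to pixel coordinates
#'
#' The full camera model: rigid transform, perspective division, lens
#' distortion, calibration matrix.
#'
#' @param K a [camera_intrinsics()].
#' @param P a [camera_pose()].
#' @param X length-3 world point or Nx3 matrix.
#' @param distorted apply lens distortion (default `TRUE`).
#' @return Nx2 matrix (or length-2 vector for a single point) of pixels.
#' @export
project_point <- function(K, P, X, distorted = TRUE) {
  single <- is.null(dim(X))
  X <- matrix(X, ncol = 3)
  Xc <- X %*% t(P$R) + matrix(P$t, nrow(X), 3, byrow = TRUE)
  if (any(Xc[, 3] <= 0))
    stop("cheirality violation: point at or behind the camera plane")
  xn <- Xc[, 1:2, drop = FALSE] / Xc[, 3]
  px <- normalized_to_pixel(K, xn, distorted = distorted)
  if (single) as.numeric(px) else px
}

# Vectorized projection without cheirality errors; returns list with px and
# depth so callers can mask invisible points.
project_points_depth <- function(K, P, X, distorted = TRUE) {
  X <- matrix(X, ncol = 3)
  Xc <- X %*% t(P$R) + matrix(P$t, nrow(X), 3, byrow = TRUE)
  z <- Xc[, 3]
  xn <- Xc[, 1:2, drop = FALSE] / ifelse(z == 0, NA_real_, z)
  px <- normalized_to_pixel(K, xn, distorted = distorted)
  list(px = px, depth = z)
}
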