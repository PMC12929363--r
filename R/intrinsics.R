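#' Camera intrinsics
#'
#' Pinhole intrinsics plus a standard radial--tangential lens distortion
#' model. Distortion coefficients follow the common `(k1, k2, p1, p2, k3)`
#' ordering (radial k1..k3, tangential p1, p2); trailing zeros may be
#' omitted. Pixel coordinates are 0-based pixel centers, x right, y down.
#'
#' @param fx,fy focal lengths in pixels (must be positive).
#' @param cx,cy principal point in pixels (inside the image).
#' @param dist numeric distortion coefficients `(k1, k2, p1, p2, k3)`;
#'   shorter vectors are zero-padded.
#' @param width,height image size in pixels.
#' @param camera_id optional identifier string.
#' @return an object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, dist = numeric(5),
                              width, height, camera_id = NA_character_) {
  stopifnot(is.numeric(fx), is.numeric(fy), length(fx) == 1, length(fy) == 1)
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point must lie inside the image")
  dist <- c(dist, numeric(5))[1:5]
  obj <- list(fx = fx, fy = fy, cx = cx, cy = cy, dist = dist,
              width = width, height = height,
              camera_id = as.character(camera_id))
  class(obj) <- "camera_intrinsics"
  obj
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics '%s': %dx%d, f=(%.1f, %.1f), c=(%.1f, %.1f)\n",
              x$camera_id, x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  if (any(x$dist != 0)) cat("  dist:", paste(signif(x$dist, 6), collapse = " "), "\n")
  invisible(x)
}

# 3x3 calibration matrix
intrinsics_matrix <- function(K) {
  matrix(c(K$fx, 0, 0, 0, K$fy, 0, K$cx, K$cy, 1), 3, 3)
}

has_distortion <- function(K) any(K$dist != 0)

# Apply lens distortion to normalized camera coordinates (Nx2).
distort_normalized <- function(K, xn) {
  xn <- matrix(xn, ncol = 2)
  d <- K$dist
  x <- xn[, 1]; y <- xn[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  xd <- x * radial + 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
  yd <- y * radial + d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
  cbind(xd, yd, deparse.level = 0)
}

# Invert the distortion model by Newton iteration on the 2D map.
undistort_normalized <- function(K, xd, tol = 1e-12, maxit = 50) {
  xd <- matrix(xd, ncol = 2)
  if (!has_distortion(K)) return(xd)
  xu <- xd
  for (it in seq_len(maxit)) {
    f <- distort_normalized(K, xu) - xd
    if (max(abs(f)) < tol) break
    # numeric 2x2 Jacobian per point, evaluated vectorized
    h <- 1e-7
    fx1 <- distort_normalized(K, cbind(xu[, 1] + h, xu[, 2]))
    fx2 <- distort_normalized(K, cbind(xu[, 1], xu[, 2] + h))
    f0 <- f + xd
    j11 <- (fx1[, 1] - f0[, 1]) / h; j21 <- (fx1[, 2] - f0[, 2]) / h
    j12 <- (fx2[, 1] - f0[, 1]) / h; j22 <- (fx2[, 2] - f0[, 2]) / h
    det <- j11 * j22 - j12 * j21
    dx <- (j22 * f[, 1] - j12 * f[, 2]) / det
    dy <- (-j21 * f[, 1] + j11 * f[, 2]) / det
    xu <- xu - cbind(dx, dy)
  }
  xu
}

#' Convert pixel coordinates to undistorted normalized coordinates
#'
#' Removes the calibration matrix and the lens distortion, returning ideal
#' normalized camera coordinates (x/z, y/z).
#'
#' @param K a [camera_intrinsics()].
#' @param px Nx2 matrix (or length-2 vector) of pixel coordinates.
#' @return Nx2 matrix of normalized coordinates.
#' @export
pixel_to_normalized <- function(K, px) {
  px <- matrix(px, ncol = 2)
  xn <- cbind((px[, 1] - K$cx) / K$fx, (px[, 2] - K$cy) / K$fy)
  undistort_normalized(K, xn)
}

#' Convert normalized coordinates to (distorted) pixel coordinates
#'
#' @param K a [camera_intrinsics()].
#' @param xn Nx2 matrix of normalized camera coordinates.
#' @param distorted apply the lens distortion model (default `TRUE`).
#' @return Nx2 matrix of pixel coordinates.
#' @export
normalized_to_pixel <- function(K, xn, distorted = TRUE) {
  xn <- matrix(xn, ncol = 2)
  if (distorted) xn <- distort_normalized(K, xn)
  cbind(xn[, 1] * K$fx + K$cx, xn[, 2] * K$fy + K$cy, deparse.level = 0)
}

#' Undistort pixel observations
#'
#' Maps distorted pixel coordinates to the pixel coordinates an ideal
#' pinhole camera with the same `K` would have produced. The calibration
#' pipeline operates on undistorted pixels throughout; distortion is applied
#' only at the image interface.
#'
#' @inheritParams pixel_to_normalized
#' @return Nx2 matrix of undistorted pixel coordinates.
#' @export
undistort_pixels <- function(K, px) {
  normalized_to_pixel(K, pixel_to_normalized(K, px), distorted = FALSE)
}
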