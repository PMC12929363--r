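# Raster rendering of marker frames. Pixels are 0-based pixel centers
# (x right, y down); image matrices are [height x width] grayscale in [0, 1].
# Anti-aliasing by regular sub-pixel supersampling, which the detector's
# 50%-level edge localization relies on for sub-pixel accuracy.

# Paint one marker into `img`. H maps marker cell coordinates
# [0, 8] x [0, 8] to image pixels. Returns the updated image.
draw_marker <- function(img, H, bits, ss = 4L) {
  nc <- nrow(bits)
  corners_cell <- matrix(c(0, 0, nc, 0, nc, nc, 0, nc), 4, 2, byrow = TRUE)
  corners <- tryCatch(apply_homography(H, corners_cell), error = function(e) NULL)
  if (is.null(corners)) return(list(img = img, clipped = TRUE, drawn = FALSE))
  Hdim <- dim(img)
  x0 <- floor(min(corners[, 1])) - 1; x1 <- ceiling(max(corners[, 1])) + 1
  y0 <- floor(min(corners[, 2])) - 1; y1 <- ceiling(max(corners[, 2])) + 1
  clipped <- x0 < 0 || y0 < 0 || x1 > Hdim[2] - 1 || y1 > Hdim[1] - 1
  cx0 <- max(x0, 0); cx1 <- min(x1, Hdim[2] - 1)
  cy0 <- max(y0, 0); cy1 <- min(y1, Hdim[1] - 1)
  if (cx0 > cx1 || cy0 > cy1) return(list(img = img, clipped = TRUE, drawn = FALSE))
  xs <- cx0:cx1; ys <- cy0:cy1
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  Hinv <- solve(H)
  acc <- matrix(0, length(ys), length(xs))
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  for (oy in off) for (ox in off) {
    q <- cbind(px + ox, py + oy, 1) %*% t(Hinv)
    u <- q[, 1] / q[, 3]; v <- q[, 2] / q[, 3]
    inside <- is.finite(u) & is.finite(v) & u >= 0 & u < nc & v >= 0 & v < nc
    val <- numeric(length(u))
    if (any(inside)) {
      ci <- pmin(pmax(floor(v[inside]), 0), nc - 1) + 1
      cj <- pmin(pmax(floor(u[inside]), 0), nc - 1) + 1
      val[inside] <- bits[cbind(ci, cj)]
    }
    acc <- acc + matrix(val, length(ys), length(xs))
  }
  acc <- acc / ss^2
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  img[ys + 1, xs + 1] <- pmax(sub, acc)
  list(img = img, clipped = clipped, drawn = TRUE)
}

#' Render one projector frame of a schedule
#'
#' Rasterizes every marker of array `array_idx` at scale index `scale_idx`
#' into a grayscale raster at the projector resolution. Each symbol instance
#' is centered on its marker center; markers clipped by the frame boundary
#' are rendered anyway and flagged in the metadata.
#'
#' @param schedule a [make_schedule()] object.
#' @param array_idx 0-based array index.
#' @param scale_idx 1-based index into the scale set.
#' @param ss supersampling factor for anti-aliasing.
#' @return list with `image` (height x width matrix in \[0, 1\]) and
#'   `markers` (data frame: marker_id, cx, cy, side_px, clipped).
#' @export
render_projector_frame <- function(schedule, array_idx, scale_idx, ss = 4L) {
  if (array_idx < 0 || array_idx >= schedule$n_arrays) stop("invalid array index")
  if (scale_idx < 1 || scale_idx > length(schedule$scales)) stop("invalid scale index")
  W <- schedule$projector_resolution[1]; H <- schedule$projector_resolution[2]
  img <- matrix(0, H, W)
  lam <- schedule$scales[scale_idx]
  side_px <- schedule$base_side * schedule$px_per_m * lam
  rows <- which(schedule$markers$array_idx == array_idx)
  meta <- schedule$markers[rows, c("marker_id", "cx", "cy")]
  meta$side_px <- side_px
  meta$clipped <- FALSE
  for (r in seq_along(rows)) {
    m <- schedule$markers[rows[r], ]
    bits <- marker_bits(m$marker_id %% 4096L)
    # marker cell coords [0,8] -> projector px (axis-aligned square)
    cell <- side_px / MSQ6_CELLS
    Hm <- matrix(c(cell, 0, 0,
                   0, cell, 0,
                   m$cx - side_px / 2, m$cy - side_px / 2, 1), 3, 3)
    res <- draw_marker(img, Hm, bits, ss = ss)
    img <- res$img
    meta$clipped[r] <- res$clipped
  }
  list(image = img, markers = meta)
}

# Homography mapping floor coordinates (meters, z = 0 plane) to undistorted
# pixel coordinates of a camera.
floor_to_image_homography <- function(K, P) {
  Km <- intrinsics_matrix(K)
  Km %*% cbind(P$R[, 1], P$R[, 2], P$t)
}

#' Render a camera view of one projected frame
#'
#' Rasterizes the markers of one (array, scale) slot as seen by a pinhole
#' camera observing the floor plane: marker geometry is mapped through the
#' projector-to-floor homography and the camera's floor-to-image homography.
#' Cameras are modeled distortion-free on this path. Markers entirely behind
#' the camera or outside the image are skipped.
#'
#' @param schedule a [make_schedule()] object.
#' @param array_idx,scale_idx frame indices as in [render_projector_frame()].
#' @param g_proj projector-to-floor homography.
#' @param K,P camera intrinsics and pose.
#' @param ss supersampling factor.
#' @return list with `image` and `markers` metadata (marker_id, clipped,
#'   drawn, center_px = true imaged center).
#' @export
render_camera_view <- function(schedule, array_idx, scale_idx,
                               g_proj, K, P, ss = 4L) {
  W <- K$width; Hh <- K$height
  img <- matrix(0, Hh, W)
  lam <- schedule$scales[scale_idx]
  side_px <- schedule$base_side * schedule$px_per_m * lam
  Hcf <- floor_to_image_homography(K, P)
  rows <- which(schedule$markers$array_idx == array_idx)
  meta <- schedule$markers[rows, c("marker_id", "cx", "cy")]
  meta$clipped <- NA
  meta$drawn <- FALSE
  meta$side_px <- NA_real_
  meta$center_u <- NA_real_; meta$center_v <- NA_real_
  for (r in seq_along(rows)) {
    m <- schedule$markers[rows[r], ]
    bits <- marker_bits(m$marker_id %% 4096L)
    cell <- side_px / MSQ6_CELLS
    Hm <- matrix(c(cell, 0, 0,
                   0, cell, 0,
                   m$cx - side_px / 2, m$cy - side_px / 2, 1), 3, 3)
    Hfull <- Hcf %*% g_proj %*% Hm
    # cheirality: all corners must project with positive depth
    cc <- matrix(c(0, 0, MSQ6_CELLS, 0, MSQ6_CELLS, MSQ6_CELLS, 0, MSQ6_CELLS),
                 4, 2, byrow = TRUE)
    w <- cbind(cc, 1) %*% t(Hfull)
    if (any(w[, 3] <= 0)) next
    res <- draw_marker(img, Hfull, bits, ss = ss)
    img <- res$img
    meta$clipped[r] <- res$clipped
    meta$drawn[r] <- res$drawn
    qq <- apply_homography(Hfull, cc)
    meta$side_px[r] <- min(sqrt(rowSums((qq - qq[c(2, 3, 4, 1), ])^2)))
    ctr <- apply_homography(Hcf %*% g_proj, c(m$cx, m$cy))
    meta$center_u[r] <- ctr[1]; meta$center_v[r] <- ctr[2]
  }
  list(image = img, markers = meta)
}
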