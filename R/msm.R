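# Multi-scale markers: one floor location projected as the same fiducial
# symbol at several scales that share an exact common center, so that at
# least one scale is detectable from any viewpoint and zoom level.

#' Euclidean pattern specification
#'
#' A square fiducial pattern with a well-defined center: the intersection of
#' the square's diagonals, which is a projective invariant and therefore
#' survives the projector-to-floor and floor-to-image homographies.
#'
#' @param symbol_id integer symbol id within the fiducial family.
#' @param base_side physical side length at scale 1, in meters on the floor.
#' @param family fiducial family identifier (only `"msq6"` is built in).
#' @return an object of class `pattern_spec`; its `center` is the square
#'   center in pattern coordinates (the origin).
#' @export
pattern_spec <- function(symbol_id, base_side = 0.05, family = "msq6") {
  if (base_side <= 0) stop("base_side must be positive")
  structure(list(family = family, symbol_id = as.integer(symbol_id),
                 center = c(0, 0), base_side = base_side),
            class = "pattern_spec")
}

#' Construct a multi-scale marker
#'
#' An MSM is a pattern together with an ordered set of scale factors; every
#' scaled instance is the image of the base pattern under the planar scaling
#' about the marker center `p`, so all instances fix `p` exactly.
#'
#' @param pattern a [pattern_spec()].
#' @param p length-2 marker center in projector image coordinates (pixels).
#' @param scales strictly increasing positive scale factors (Lambda).
#' @param marker_id global integer marker id (defaults to the symbol id).
#' @return an object of class `msm_spec`.
#' @export
make_msm <- function(pattern, p, scales, marker_id = pattern$symbol_id) {
  scales <- as.numeric(scales)
  if (length(scales) < 1 || any(scales <= 0)) stop("invalid scale: all scales must be positive")
  if (is.unsorted(scales, strictly = TRUE)) stop("scales must be strictly increasing")
  structure(list(marker_id = as.integer(marker_id), pattern = pattern,
                 center_p = as.numeric(p), scales = scales),
            class = "msm_spec")
}

#' Corners of one scaled instance of an MSM
#'
#' Applies the scaling homography about the marker center to the base
#' square's corners. `px_per_m` converts the physical base side to projector
#' pixels.
#'
#' @param msm an [make_msm()] object.
#' @param scale_idx index into the scale set.
#' @param px_per_m projector pixels per floor meter.
#' @return 4x2 matrix of corner positions (projector px), counterclockwise.
#' @export
msm_instance_corners <- function(msm, scale_idx, px_per_m = 480) {
  lam <- msm$scales[scale_idx]
  half <- msm$pattern$base_side * px_per_m / 2
  base <- matrix(c(-half, -half, half, -half, half, half, -half, half),
                 4, 2, byrow = TRUE)
  base <- sweep(base, 2, msm$center_p, "+")
  S <- scaling_homography(msm$center_p, lam)
  apply_homography(S, base)
}

#' Build a timed projection schedule of MSM arrays
#'
#' Arrays of `markers_per_array` MSMs are laid out on a regular base grid
#' spanning the projector image with uniform margins; each successive array
#' is slightly offset, the offsets cycling through a sub-grid of the base
#' cell so that `n_arrays` arrays tile the floor densely. The default
#' configuration (100 arrays x 32 markers, offsets on a 10x10 sub-grid)
#' produces a dense grid of 3200 distinct marker centers.
#'
#' @param n_arrays number of arrays projected in sequence.
#' @param markers_per_array markers per array (laid out `grid_nx` x `grid_ny`).
#' @param scales scale factor set Lambda (strictly increasing).
#' @param projector_resolution c(width, height) in pixels.
#' @param base_side physical marker side at scale 1 in meters.
#' @param px_per_m projector pixels per floor meter.
#' @param grid_nx,grid_ny base grid layout; must satisfy
#'   `grid_nx * grid_ny == markers_per_array`.
#' @param margin_px uniform margin around the base grid.
#' @param offset_grid offsets cycle over an `offset_grid` x `offset_grid`
#'   sub-grid of one base cell.
#' @param slot_duration seconds each (array, scale) frame is displayed.
#' @return an object of class `projection_schedule` with a `markers` data
#'   frame (marker_id, array_idx, within_idx, cx, cy) and layout metadata.
#' @export
make_schedule <- function(n_arrays = 100, markers_per_array = 32,
                          scales = c(1.0, 1.4, 2.0, 3.0, 4.0, 6.0, 8.0),
                          projector_resolution = c(1920, 1080),
                          base_side = 0.05, px_per_m = 480,
                          grid_nx = 8, grid_ny = 4, margin_px = 120,
                          offset_grid = 10, slot_duration = 0.1) {
  stopifnot(grid_nx * grid_ny == markers_per_array)
  if (n_arrays > offset_grid^2)
    stop("offset sub-grid too small for the requested number of arrays")
  W <- projector_resolution[1]; H <- projector_resolution[2]
  cell_w <- (W - 2 * margin_px) / grid_nx
  cell_h <- (H - 2 * margin_px) / grid_ny
  step_x <- cell_w / offset_grid
  step_y <- cell_h / offset_grid
  rows <- vector("list", n_arrays)
  for (a in seq_len(n_arrays) - 1L) {
    kx <- a %% offset_grid
    ky <- a %/% offset_grid
    ox <- (kx - (offset_grid - 1) / 2) * step_x
    oy <- (ky - (offset_grid - 1) / 2) * step_y
    j <- rep(seq_len(grid_nx) - 1L, times = grid_ny)
    i <- rep(seq_len(grid_ny) - 1L, each = grid_nx)
    within <- i * grid_nx + j
    rows[[a + 1L]] <- data.frame(
      marker_id = a * markers_per_array + within,
      array_idx = a, within_idx = within,
      cx = margin_px + (j + 0.5) * cell_w + ox,
      cy = margin_px + (i + 0.5) * cell_h + oy)
  }
  markers <- do.call(rbind, rows)
  if (anyDuplicated(markers[, c("cx", "cy")]))
    stop("schedule invalid: duplicate marker centers after offsetting")
  if (anyDuplicated(markers$marker_id))
    stop("schedule invalid: duplicate marker ids")
  # clipping check at the largest scale
  half_max <- base_side * px_per_m * max(scales) / 2
  clipped <- markers$cx - half_max < 0 | markers$cx + half_max > W |
             markers$cy - half_max < 0 | markers$cy + half_max > H
  markers$clipped_at_max_scale <- clipped
  structure(list(n_arrays = n_arrays, markers_per_array = markers_per_array,
                 scales = scales, projector_resolution = projector_resolution,
                 base_side = base_side, px_per_m = px_per_m,
                 grid_nx = grid_nx, grid_ny = grid_ny, margin_px = margin_px,
                 offset_grid = offset_grid, slot_duration = slot_duration,
                 markers = markers),
            class = "projection_schedule")
}

#' @export
print.projection_schedule <- function(x, ...) {
  cat(sprintf(paste0("projection_schedule: %d arrays x %d markers = %d centers, ",
                     "|Lambda| = %d (%.3g-%.3g m), projector %dx%d\n"),
              x$n_arrays, x$markers_per_array, nrow(x$markers),
              length(x$scales), x$base_side * min(x$scales),
              x$base_side * max(x$scales),
              x$projector_resolution[1], x$projector_resolution[2]))
  invisible(x)
}

# msm_spec for one schedule entry
schedule_msm <- function(schedule, row) {
  m <- schedule$markers[row, ]
  make_msm(pattern_spec(m$marker_id %% 4096L, schedule$base_side),
           c(m$cx, m$cy), schedule$scales, marker_id = m$marker_id)
}

#' Default projector-to-floor homography
#'
#' Maps projector pixels to floor meters with the projector principal point
#' at the floor origin: a scale-and-center map at `px_per_m`, with the floor
#' Y axis flipped. The flip makes the map orientation-reversing, as the
#' floor-to-image homography of any ceiling-mounted projector (or camera)
#' looking down at the z = 0 plane is, so that cameras above the floor see
#' the projected symbols right-reading. Stands in for the (unknown and
#' never required) true projector pose; the method is projector-calibration
#' free, so any such choice only fixes the simulated floor layout.
#'
#' @param px_per_m projector pixels per floor meter.
#' @param projector_resolution c(width, height) in pixels.
#' @return 3x3 homography (projector px -> floor meters).
#' @export
projector_floor_homography <- function(px_per_m = 480,
                                       projector_resolution = c(1920, 1080)) {
  matrix(c(1 / px_per_m, 0, 0,
           0, -1 / px_per_m, 0,
           -projector_resolution[1] / 2 / px_per_m,
           projector_resolution[2] / 2 / px_per_m, 1), 3, 3)
}

#' Floor coordinates of all marker centers
#'
#' Maps every marker center through the projector-to-floor homography and
#' embeds the result in the z = 0 floor plane.
#'
#' @param schedule a [make_schedule()] object.
#' @param g_proj 3x3 projector-to-floor homography (pixels to meters).
#' @return data frame with columns marker_id, X, Y, Z (Z identically 0).
#' @export
floor_coordinates <- function(schedule, g_proj = projector_floor_homography(
                                schedule$px_per_m, schedule$projector_resolution)) {
  if (abs(det(g_proj)) < 1e-14) stop("invalid homography: singular projector map")
  xy <- apply_homography(g_proj, as.matrix(schedule$markers[, c("cx", "cy")]))
  data.frame(marker_id = schedule$markers$marker_id,
             X = xy[, 1], Y = xy[, 2], Z = 0)
}
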