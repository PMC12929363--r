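# From raw per-frame detections to one observation per (camera, marker) and
# cross-view correspondence tracks.

#' Fuse multi-scale detections of one marker into a single observation
#'
#' The imaged center of every scaled instance of an MSM coincides (the
#' diagonal-intersection center is invariant to the scaling family), so the
#' per-scale centers are aggregated robustly: coordinate-wise median with
#' MAD-based outlier rejection at 3.5 robust sigmas, plus an absolute gate.
#' Frames showing the same (array, scale) slot are averaged before fusion.
#'
#' @param centers Nx2 matrix of per-scale detected centers (pixels).
#' @param scales the scale factor of each row.
#' @param gate_px absolute rejection gate on the residual to the aggregate
#'   and on the final spread (default 2 px).
#' @return list with `center` (length-2), `spread_px` (RMS residual of the
#'   kept centers), `scales_seen`, `n_used`; or `NULL` when the fused
#'   observation fails the gate.
#' @export
fuse_scales <- function(centers, scales = seq_len(nrow(centers)), gate_px = 2) {
  centers <- matrix(centers, ncol = 2)
  n <- nrow(centers)
  stopifnot(n >= 1)
  med <- c(median(centers[, 1]), median(centers[, 2]))
  r <- sqrt((centers[, 1] - med[1])^2 + (centers[, 2] - med[2])^2)
  sigma <- 1.4826 * median(r)
  keep <- r <= pmax(3.5 * sigma, 1e-9) & r <= gate_px * 2
  if (!any(keep)) keep <- r == min(r)
  agg <- colMeans(centers[keep, , drop = FALSE])
  res <- sqrt((centers[keep, 1] - agg[1])^2 + (centers[keep, 2] - agg[2])^2)
  spread <- sqrt(mean(res^2))
  if (spread > gate_px) return(NULL)
  list(center = as.numeric(agg), spread_px = spread,
       scales_seen = sort(unique(scales[keep])), n_used = sum(keep))
}

#' Raw detections to fused marker observations
#'
#' Groups a raw detection table by (camera, symbol), computes the
#' diagonal-intersection center of every detection, averages repeated frames
#' of the same scale slot, and fuses across scales with [fuse_scales()].
#' Scale slots are identified from `frame_idx` when a schedule is given
#' (frames are projected in ascending scale order within each array slot).
#'
#' @param detections data frame with columns camera_id, frame_idx,
#'   symbol_id, x1..y4 (as produced by [detect_frame()] plus camera/frame
#'   columns).
#' @param schedule optional [make_schedule()]; maps frame_idx to scale slots
#'   and symbol ids to global marker ids.
#' @param gate_px fusion gate in pixels.
#' @return data frame of observations: camera_id, marker_id, x, y,
#'   spread_px, n_scales, n_frames.
#' @export
detections_to_observations <- function(detections, schedule = NULL, gate_px = 2) {
  need <- c("camera_id", "frame_idx", "symbol_id",
            "x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")
  stopifnot(all(need %in% names(detections)))
  if (!nrow(detections)) {
    return(data.frame(camera_id = character(), marker_id = integer(),
                      x = numeric(), y = numeric(), spread_px = numeric(),
                      n_scales = integer(), n_frames = integer()))
  }
  nsc <- if (!is.null(schedule)) length(schedule$scales) else 1L
  ctr <- t(apply(detections[, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")],
                 1, function(v) {
                   tryCatch(center_from_corners(matrix(v, 4, 2, byrow = TRUE)),
                            error = function(e) c(NA_real_, NA_real_))
                 }))
  det <- detections
  det$cx <- ctr[, 1]; det$cy <- ctr[, 2]
  det <- det[stats::complete.cases(det[, c("cx", "cy")]), ]
  if (!is.null(schedule)) {
    # the symbol id encodes (array, within-array) injectively, so it is the
    # global marker id; the scale slot follows from the frame counter
    det$marker_id <- det$symbol_id
    det$scale_slot <- det$frame_idx %% nsc
  } else {
    det$marker_id <- det$symbol_id
    det$scale_slot <- det$frame_idx
  }
  out <- list()
  for (grp in split(det, list(det$camera_id, det$marker_id), drop = TRUE)) {
    # average repeated frames of the same scale slot
    per_slot <- do.call(rbind, lapply(split(grp, grp$scale_slot), function(g)
      data.frame(slot = g$scale_slot[1], cx = mean(g$cx), cy = mean(g$cy))))
    fused <- fuse_scales(as.matrix(per_slot[, c("cx", "cy")]),
                         scales = per_slot$slot, gate_px = gate_px)
    if (is.null(fused)) next
    out[[length(out) + 1]] <- data.frame(
      camera_id = grp$camera_id[1], marker_id = grp$marker_id[1],
      x = fused$center[1], y = fused$center[2],
      spread_px = fused$spread_px, n_scales = length(fused$scales_seen),
      n_frames = nrow(grp))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(camera_id = character(), marker_id = integer(), x = numeric(),
               y = numeric(), spread_px = numeric(), n_scales = integer(),
               n_frames = integer())
  rownames(res) <- NULL
  res[order(res$camera_id, res$marker_id), , drop = FALSE]
}

#' Build cross-view correspondence tracks
#'
#' One track per marker id: the set of per-camera observations of that
#' marker's floor point. Tracks seen by fewer than two cameras are retained
#' but flagged unusable for calibration.
#'
#' @param observations data frame with columns camera_id, marker_id, x, y
#'   (one row per camera-marker pair).
#' @return object of class `observation_tracks`: the observation table plus
#'   a per-track summary (`tracks`: marker_id, length, usable).
#' @export
build_tracks <- function(observations) {
  stopifnot(all(c("camera_id", "marker_id", "x", "y") %in% names(observations)))
  if (anyDuplicated(observations[, c("camera_id", "marker_id")]))
    stop("input integrity error: duplicate (camera, marker) observations")
  len <- table(observations$marker_id)
  tracks <- data.frame(marker_id = as.integer(names(len)),
                       length = as.integer(len))
  tracks$usable <- tracks$length >= 2
  structure(list(observations = observations[order(observations$marker_id,
                                                   observations$camera_id), ],
                 tracks = tracks[order(tracks$marker_id), ]),
            class = "observation_tracks")
}

#' @export
print.observation_tracks <- function(x, ...) {
  cat(sprintf("observation_tracks: %d observations, %d tracks (%d usable), %d cameras\n",
              nrow(x$observations), nrow(x$tracks), sum(x$tracks$usable),
              length(unique(x$observations$camera_id))))
  invisible(x)
}

# correspondence count for each camera pair
pair_correspondence_counts <- function(tracks) {
  obs <- tracks$observations
  cams <- sort(unique(obs$camera_id))
  out <- expand.grid(camera_a = cams, camera_b = cams,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[out$camera_a < out$camera_b, ]
  bym <- split(obs$camera_id, obs$marker_id)
  out$n_shared <- vapply(seq_len(nrow(out)), function(i) {
    sum(vapply(bym, function(cs) out$camera_a[i] %in% cs && out$camera_b[i] %in% cs,
               logical(1)))
  }, integer(1))
  rownames(out) <- NULL
  out
}
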