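# Pose-accuracy metrics and the held-out evaluation protocol. All
# comparisons remove the gauge freedom first: calibration from image
# measurements alone cannot determine a global similarity transform, so
# estimated and reference poses are aligned by a closed-form Sim(3) fit on
# the camera centers before errors are measured.

#' Sim(3)-aligned pose error report
#'
#' Fits a Sim(3) (Umeyama) on the camera centers mapping estimated to
#' ground-truth, then reports per-camera translation errors (aligned center
#' distance, meters) and rotation errors (geodesic angle between aligned
#' orientations, degrees), and their RMSEs.
#'
#' @param estimated,ground_truth named lists of [camera_pose()] sharing at
#'   least 3 camera ids.
#' @return object of class `pose_error_report` with fields
#'   `rotation_rmse_deg`, `translation_rmse_m`, `per_camera` (data frame),
#'   `alignment` (the fitted `sim3`).
#' @export
pose_error <- function(estimated, ground_truth) {
  common <- intersect(names(estimated), names(ground_truth))
  if (length(common) < 3)
    stop("alignment impossible: fewer than 3 common cameras")
  ce <- t(vapply(estimated[common], pose_center, numeric(3)))
  cg <- t(vapply(ground_truth[common], pose_center, numeric(3)))
  S <- umeyama_sim3(ce, cg)
  ca <- apply_sim3(S, ce)
  trans_err <- sqrt(rowSums((ca - cg)^2))
  rot_err <- vapply(common, function(cid) {
    Ra <- estimated[[cid]]$R %*% t(S$R)   # orientation in the target frame
    rotation_angle(Ra, ground_truth[[cid]]$R) * 180 / pi
  }, numeric(1))
  structure(list(
    rotation_rmse_deg = sqrt(mean(rot_err^2)),
    translation_rmse_m = sqrt(mean(trans_err^2)),
    per_camera = data.frame(camera_id = common,
                            rotation_err_deg = as.numeric(rot_err),
                            translation_err_m = as.numeric(trans_err),
                            row.names = NULL),
    alignment = S), class = "pose_error_report")
}

#' @export
print.pose_error_report <- function(x, ...) {
  cat(sprintf("pose_error_report over %d cameras: rotation RMSE %.6g deg, translation RMSE %.6g m\n",
              nrow(x$per_camera), x$rotation_rmse_deg, x$translation_rmse_m))
  invisible(x)
}

#' Evaluate fixed poses on independent held-out correspondences
#'
#' The independent-dataset protocol: with the calibrated poses frozen,
#' held-out tracks are triangulated pairwise between cameras (coordinate-
#' wise median over all pairs as the initial estimate), then refined by
#' point-only nonlinear least squares on the total reprojection error.
#' Reported are per-camera mean reprojection errors and the success rate:
#' the percentage of cameras whose mean error falls below each threshold.
#' Cameras present in the held-out data but missing a pose count as failing
#' every threshold.
#'
#' @param poses named list of [camera_pose()].
#' @param intrinsics named list of [camera_intrinsics()].
#' @param heldout_tracks an [build_tracks()] object, disjoint from the
#'   calibration data.
#' @param thresholds success thresholds in pixels.
#' @return object of class `success_report`: `rates` (percent per
#'   threshold), `per_camera` mean errors, `points` (refined 3D points),
#'   `n_skipped` tracks seen by < 2 calibrated cameras.
#' @export
evaluate_on_heldout <- function(poses, intrinsics, heldout_tracks,
                                thresholds = c(0.5, 2, 5)) {
  obs <- prepare_observations(heldout_tracks, intrinsics)
  all_cams <- sort(unique(obs$camera_id))
  cams <- intersect(all_cams, names(poses))
  K_ideal <- lapply(intrinsics, ideal_intrinsics)
  oc <- obs[obs$camera_id %in% cams, ]
  cnt <- table(oc$marker_id)
  ids <- as.integer(names(cnt)[cnt >= 2])
  n_skipped <- length(unique(obs$marker_id)) - length(ids)
  pts <- matrix(NA_real_, length(ids), 3)
  for (j in seq_along(ids)) {
    rows <- which(oc$marker_id == ids[j])
    ps <- poses[oc$camera_id[rows]]
    xn <- cbind(oc$xn[rows], oc$yn[rows])
    m <- length(rows)
    ests <- list()
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      X <- tryCatch(triangulate_linear(ps[c(a, b)], xn[c(a, b), , drop = FALSE]),
                    error = function(e) NULL)
      if (!is.null(X)) ests[[length(ests) + 1]] <- X
    }
    if (!length(ests)) next
    E <- do.call(rbind, ests)
    X0 <- apply(E, 2, median)
    pts[j, ] <- refine_point_fixed_poses(
      X0, ps, K_ideal[oc$camera_id[rows]],
      cbind(oc$xu[rows], oc$yu[rows]))
  }
  ok <- stats::complete.cases(pts)
  # per-camera mean reprojection error
  per_cam <- setNames(rep(Inf, length(all_cams)), all_cams)
  for (cid in cams) {
    rows <- which(oc$camera_id == cid & oc$marker_id %in% ids[ok])
    if (!length(rows)) next
    X <- pts[match(oc$marker_id[rows], ids), , drop = FALSE]
    pr <- project_points_depth(K_ideal[[cid]], poses[[cid]], X, distorted = FALSE)
    e <- sqrt((pr$px[, 1] - oc$xu[rows])^2 + (pr$px[, 2] - oc$yu[rows])^2)
    e[pr$depth <= 0] <- Inf
    per_cam[cid] <- mean(e)
  }
  rates <- success_rates(per_cam, thresholds)
  pts_df <- data.frame(marker_id = ids[ok], X = pts[ok, 1], Y = pts[ok, 2],
                       Z = pts[ok, 3], row.names = NULL)
  structure(list(thresholds = thresholds,
                 rates = setNames(rates, paste0("<", thresholds, "px")),
                 per_camera = data.frame(camera_id = all_cams,
                                         mean_reproj_px = as.numeric(per_cam),
                                         row.names = NULL),
                 points = pts_df, n_skipped = n_skipped),
            class = "success_report")
}

#' Success rates from per-camera mean reprojection errors
#'
#' Percentage of cameras whose mean reprojection error lies below each
#' threshold; non-finite errors (unregistered cameras) fail every
#' threshold. Monotone non-decreasing in the threshold by construction.
#'
#' @param per_camera_errors numeric vector of mean errors in pixels.
#' @param thresholds thresholds in pixels.
#' @return named numeric vector of percentages.
#' @export
success_rates <- function(per_camera_errors, thresholds = c(0.5, 2, 5)) {
  vapply(thresholds, function(th)
    100 * mean(is.finite(per_camera_errors) & per_camera_errors < th),
    numeric(1))
}

# point-only Gauss-Newton with frozen poses
refine_point_fixed_poses <- function(X, poses, Ks, pxu, maxit = 25) {
  m <- length(poses)
  for (it in seq_len(maxit)) {
    r <- numeric(2 * m); J <- matrix(0, 2 * m, 3)
    for (i in seq_len(m)) {
      P <- poses[[i]]; K <- Ks[[i]]
      Xc <- as.numeric(P$R %*% X + P$t)
      if (Xc[3] <= 1e-12) return(X)
      u <- K$fx * Xc[1] / Xc[3] + K$cx
      v <- K$fy * Xc[2] / Xc[3] + K$cy
      r[2 * i - 1] <- u - pxu[i, 1]; r[2 * i] <- v - pxu[i, 2]
      J[2 * i - 1, ] <- (K$fx * c(1 / Xc[3], 0, -Xc[1] / Xc[3]^2)) %*% P$R
      J[2 * i, ] <- (K$fy * c(0, 1 / Xc[3], -Xc[2] / Xc[3]^2)) %*% P$R
    }
    step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(3), -crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    X <- X + as.numeric(step)
    if (max(abs(step)) < 1e-13) break
  }
  X
}

#' @export
print.success_report <- function(x, ...) {
  cat("success_report:",
      paste(sprintf("%s: %.1f%%", names(x$rates), x$rates), collapse = ", "), "\n")
  invisible(x)
}

#' Compare two point clouds after Sim(3) alignment
#'
#' Matches the two clouds by marker id, aligns cloud `a` to cloud `b` with
#' [umeyama_sim3()] on the common subset, and reports Euclidean error
#' statistics.
#'
#' @param points_a,points_b data frames with columns marker_id, X, Y, Z.
#' @param probs percentile levels for the error summary.
#' @return list with `mean_error`, `percentiles`, `per_point` errors and
#'   the `alignment`.
#' @export
compare_point_clouds <- function(points_a, points_b,
                                 probs = c(0.5, 0.9, 0.95)) {
  common <- intersect(points_a$marker_id, points_b$marker_id)
  if (length(common) < 3)
    stop("alignment impossible: fewer than 3 common points")
  A <- as.matrix(points_a[match(common, points_a$marker_id), c("X", "Y", "Z")])
  B <- as.matrix(points_b[match(common, points_b$marker_id), c("X", "Y", "Z")])
  S <- umeyama_sim3(A, B)
  e <- sqrt(rowSums((apply_sim3(S, A) - B)^2))
  list(mean_error = mean(e),
       percentiles = stats::quantile(e, probs = probs),
       per_point = data.frame(marker_id = common, error = e),
       alignment = S)
}
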