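# Multi-view triangulation. The linear (DLT) solution is refined by
# Gauss-Newton on the summed squared pixel reprojection error.

# Linear triangulation from normalized (undistorted, intrinsics-removed)
# observations. poses: list of camera_pose; xn: Mx2 matrix, one row per view.
triangulate_linear <- function(poses, xn) {
  m <- length(poses)
  A <- matrix(0, 2 * m, 4)
  for (i in seq_len(m)) {
    P <- cbind(poses[[i]]$R, poses[[i]]$t)
    A[2 * i - 1, ] <- xn[i, 1] * P[3, ] - P[1, ]
    A[2 * i, ]     <- xn[i, 2] * P[3, ] - P[2, ]
  }
  sv <- svd(A, nu = 0, nv = 4)
  X <- sv$v[, 4]
  if (abs(X[4]) < 1e-12)
    stop("ill-conditioned triangulation: point at infinity")
  X[1:3] / X[4]
}

#' Triangulate a 3D point from two or more views
#'
#' Linear multi-view triangulation (DLT on normalized coordinates) refined
#' by Gauss-Newton minimization of the summed squared pixel reprojection
#' error. Observations are undistorted internally before use.
#'
#' @param poses list of [camera_pose()] (length >= 2, distinct centers).
#' @param intrinsics list of [camera_intrinsics()], one per pose.
#' @param obs Mx2 matrix of pixel observations (distorted), one row per view.
#' @param refine run the nonlinear refinement (default `TRUE`).
#' @return length-3 world point with positive depth in all views.
#' @export
triangulate_point <- function(poses, intrinsics, obs, refine = TRUE) {
  m <- length(poses)
  stopifnot(m >= 2, length(intrinsics) == m)
  obs <- matrix(obs, ncol = 2)
  centers <- t(vapply(poses, pose_center, numeric(3)))
  maxbase <- max(stats::dist(centers))
  if (maxbase < 1e-9)
    stop("ill-conditioned triangulation: camera centers coincide (zero baseline)")
  xn <- t(vapply(seq_len(m), function(i)
    as.numeric(pixel_to_normalized(intrinsics[[i]], obs[i, ])), numeric(2)))
  X <- triangulate_linear(poses, xn)
  if (refine) {
    # Gauss-Newton on pixel residuals
    for (it in 1:20) {
      r <- numeric(2 * m); J <- matrix(0, 2 * m, 3)
      for (i in seq_len(m)) {
        K <- intrinsics[[i]]; P <- poses[[i]]
        Xc <- as.numeric(P$R %*% X + P$t)
        if (Xc[3] <= 1e-12) break
        u <- K$fx * Xc[1] / Xc[3] + K$cx
        v <- K$fy * Xc[2] / Xc[3] + K$cy
        ou <- undistort_pixels(K, obs[i, ])
        r[2 * i - 1] <- u - ou[1]; r[2 * i] <- v - ou[2]
        dudXc <- K$fx * c(1 / Xc[3], 0, -Xc[1] / Xc[3]^2)
        dvdXc <- K$fy * c(0, 1 / Xc[3], -Xc[2] / Xc[3]^2)
        J[2 * i - 1, ] <- dudXc %*% P$R
        J[2 * i, ] <- dvdXc %*% P$R
      }
      H <- crossprod(J) + 1e-12 * diag(3)
      step <- tryCatch(solve(H, -crossprod(J, r)), error = function(e) NULL)
      if (is.null(step)) break
      X <- X + as.numeric(step)
      if (max(abs(step)) < 1e-12) break
    }
  }
  depths <- vapply(poses, function(P) (P$R %*% X + P$t)[3], numeric(1))
  if (any(depths <= 0))
    stop("cheirality failure: triangulated point behind a camera")
  X
}

# Batch linear triangulation, vectorized across points.
# obs: data.frame with columns cam (index into poses), pt (point index),
# xn1, xn2 (normalized undistorted coords). Returns list(X = Nx3, ok).
triangulate_batch <- function(poses, obs, pt_ids) {
  X <- matrix(NA_real_, length(pt_ids), 3)
  ok <- logical(length(pt_ids))
  split_idx <- split(seq_len(nrow(obs)), factor(obs$pt, levels = pt_ids))
  for (j in seq_along(pt_ids)) {
    rows <- split_idx[[j]]
    if (length(rows) < 2) next
    ps <- poses[obs$cam[rows]]
    xn <- cbind(obs$xn1[rows], obs$xn2[rows])
    Xj <- tryCatch(triangulate_linear(ps, xn), error = function(e) NULL)
    if (is.null(Xj)) next
    z <- vapply(ps, function(P) (P$R %*% Xj + P$t)[3], numeric(1))
    if (all(z > 0)) { X[j, ] <- Xj; ok[j] <- TRUE }
  }
  list(X = X, ok = ok)
}

# Minimum pairwise triangulation angle (radians) of a point seen from a set
# of camera centers.
triangulation_angle <- function(X, centers) {
  d <- sweep(centers, 2, X)
  d <- d / sqrt(rowSums(d^2))
  m <- nrow(d)
  best <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ct <- max(-1, min(1, sum(d[i, ] * d[j, ])))
    best <- max(best, acos(ct))
  }
  best
}
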