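# Camera resectioning (Perspective-n-Point). The minimal/linear solvers
# handle both general and planar 3D configurations -- planar support is
# essential here because all marker centers lie on the floor.

# Pose from >= 4 coplanar points via the plane-to-image homography.
# pts3d: Nx3 (coplanar), xn: Nx2 normalized image coords.
pnp_planar <- function(pts3d, xn) {
  ctr <- colMeans(pts3d)
  Xc <- sweep(pts3d, 2, ctr)
  sv <- svd(Xc, nu = 0)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  uv <- cbind(Xc %*% e1, Xc %*% e2)
  H <- homography_dlt(uv, xn)
  # H ~ [r1 r2 t] for plane coords (u, v, 1)
  h1 <- H[, 1]; h2 <- H[, 2]; h3 <- H[, 3]
  s <- 2 / (vnorm(h1) + vnorm(h2))
  r1 <- s * h1; r2 <- s * h2; t <- s * h3
  R <- closest_rotation(cbind(r1, r2, cross3(r1, r2)))
  if ((R %*% uv2world_depth_probe(uv) + t)[3] < 0) {
    # flip: homography scale sign ambiguity
    R <- closest_rotation(cbind(-r1, -r2, cross3(-r1, -r2)))
    t <- -s * h3
  }
  # compose plane frame -> world frame: X = ctr + u e1 + v e2
  # x_cam = R_plane (u,v,0) + t, so world->cam: R_w = R_plane %*% B^T with
  # B = [e1 e2 e3], t_w = t - R_w ctr
  e3 <- cross3(e1, e2)
  B <- cbind(e1, e2, e3)
  Rw <- R %*% t(B)
  tw <- t - Rw %*% ctr
  camera_pose(closest_rotation(Rw), as.numeric(tw))
}

uv2world_depth_probe <- function(uv) c(colMeans(uv), 0)

# Direct linear transform pose from >= 6 general-position points.
pnp_dlt <- function(pts3d, xn) {
  n <- nrow(pts3d)
  stopifnot(n >= 6)
  A <- matrix(0, 2 * n, 12)
  Xh <- cbind(pts3d, 1)
  z <- matrix(0, n, 4)
  A[seq(1, 2 * n, 2), ] <- cbind(Xh, z, -xn[, 1] * Xh)
  A[seq(2, 2 * n, 2), ] <- cbind(z, Xh, -xn[, 2] * Xh)
  sv <- svd(A, nu = 0, nv = 12)
  P <- matrix(sv$v[, 12], 3, 4, byrow = TRUE)
  M <- P[, 1:3]
  if (det(M) < 0) P <- -P
  s <- (svd(P[, 1:3])$d)[2]
  P <- P / s
  R <- closest_rotation(P[, 1:3])
  camera_pose(R, P[, 4])
}

# Nonlinear pose refinement on pixel residuals (Gauss-Newton, axis-angle
# increments composed onto the current rotation).
refine_pose <- function(K, pose, pts3d, px_undist, maxit = 30) {
  R <- pose$R; t <- pose$t
  n <- nrow(pts3d)
  for (it in seq_len(maxit)) {
    Xc <- pts3d %*% t(R) + matrix(t, n, 3, byrow = TRUE)
    z <- Xc[, 3]
    if (any(z <= 1e-9)) break
    u <- K$fx * Xc[, 1] / z + K$cx
    v <- K$fy * Xc[, 2] / z + K$cy
    r <- c(rbind(u - px_undist[, 1], v - px_undist[, 2]))
    J <- matrix(0, 2 * n, 6)
    iz <- 1 / z
    du <- cbind(K$fx * iz, 0, -K$fx * Xc[, 1] * iz^2)
    dv <- cbind(0, K$fy * iz, -K$fy * Xc[, 2] * iz^2)
    # dXc/dw = -[Xc - t]_x (rotation applied about the camera: Xc = R X + t,
    # increment R <- exp(w) R gives dXc/dw = -[R X]_x = -[Xc - t]_x)
    Y <- Xc - matrix(t, n, 3, byrow = TRUE)
    # J_w columns: cross products
    Jw_u <- cbind(du[, 2] * (-Y[, 3]) + du[, 3] * Y[, 2],
                  du[, 1] * Y[, 3] + du[, 3] * (-Y[, 1]),
                  du[, 1] * (-Y[, 2]) + du[, 2] * Y[, 1])
    Jw_v <- cbind(dv[, 2] * (-Y[, 3]) + dv[, 3] * Y[, 2],
                  dv[, 1] * Y[, 3] + dv[, 3] * (-Y[, 1]),
                  dv[, 1] * (-Y[, 2]) + dv[, 2] * Y[, 1])
    J[seq(1, 2 * n, 2), ] <- cbind(Jw_u, du)
    J[seq(2, 2 * n, 2), ] <- cbind(Jw_v, dv)
    H <- crossprod(J) + 1e-9 * diag(6)
    step <- tryCatch(solve(H, -crossprod(J, r)), error = function(e) NULL)
    if (is.null(step)) break
    w <- as.numeric(step[1:3]); dt <- as.numeric(step[4:6])
    R <- rot_from_rotvec(w) %*% R
    t <- t + dt
    if (max(abs(step)) < 1e-13) break
  }
  camera_pose(closest_rotation(R), t)
}

#' Robust camera resectioning (PnP) with RANSAC
#'
#' Estimates a camera pose from 3D--2D correspondences. Minimal samples use
#' a planar homography-based solver when the sampled points are (near-)
#' coplanar -- the common case for floor markers -- and a 6-point DLT
#' otherwise; the winning hypothesis is refined on all inliers by nonlinear
#' minimization of the pixel reprojection error.
#'
#' @param K a [camera_intrinsics()].
#' @param pts3d Nx3 matrix of world points.
#' @param px Nx2 matrix of (distorted) pixel observations.
#' @param threshold_px inlier reprojection threshold in pixels (default 3).
#' @param seed integer RNG seed.
#' @param min_inlier_ratio registration fails below this inlier fraction.
#' @param max_iter RANSAC iteration cap.
#' @return list with `pose` ([camera_pose()]) and `inliers` (logical mask).
#' @export
pnp_ransac <- function(K, pts3d, px, threshold_px = 3, seed = 1L,
                       min_inlier_ratio = 0.3, max_iter = 10000L) {
  pts3d <- matrix(pts3d, ncol = 3); px <- matrix(px, ncol = 2)
  n <- nrow(pts3d)
  if (n < 4) stop("insufficient data: need at least 4 points")
  pxu <- undistort_pixels(K, px)
  xn <- pixel_to_normalized(K, px)
  ctr <- colMeans(pts3d)
  svd_all <- svd(sweep(pts3d, 2, ctr), nu = 0)
  # near-coplanar configurations (noisy floor points included) must take the
  # homography route: the 6-point DLT is degenerate there
  planar_ratio <- 0.05
  planar_all <- svd_all$d[3] < 1e-4 * max(svd_all$d[1], 1e-12)
  samp_size <- if (planar_all) 4L else 6L
  reproj_err <- function(pose) {
    pr <- project_points_depth(K, pose, pts3d, distorted = FALSE)
    e <- sqrt((pr$px[, 1] - pxu[, 1])^2 + (pr$px[, 2] - pxu[, 2])^2)
    e[!is.finite(e) | pr$depth <= 0] <- Inf
    e
  }
  with_seed(seed, {
    best_inl <- NULL; best_cnt <- -1L
    it <- 0L; needed <- max_iter
    while (it < needed && it < max_iter) {
      it <- it + 1L
      idx <- sample.int(n, samp_size)
      pose <- tryCatch({
        S <- pts3d[idx, , drop = FALSE]
        sv <- svd(sweep(S, 2, colMeans(S)), nu = 0)
        if (samp_size == 4L || sv$d[3] < planar_ratio * max(sv$d[1], 1e-12)) {
          pnp_planar(S, xn[idx, , drop = FALSE])
        } else {
          pnp_dlt(S, xn[idx, , drop = FALSE])
        }
      }, error = function(e) NULL)
      if (is.null(pose)) next
      e <- reproj_err(pose)
      inl <- e < threshold_px
      cnt <- sum(inl)
      if (cnt > best_cnt) {
        best_cnt <- cnt; best_inl <- inl
        needed <- ransac_iterations(cnt / n, samp_size, max_iter)
      }
    }
    if (best_cnt < 4) stop("registration failure: no PnP hypothesis found 4 inliers")
    # refine on inliers, refresh mask, refine once more
    pose <- refine_pose_from_subset(K, pts3d, xn, pxu, best_inl)
    inl <- reproj_err(pose) < threshold_px
    if (sum(inl) >= 4) pose <- refine_pose_from_subset(K, pts3d, xn, pxu, inl)
    else inl <- best_inl
    if (mean(inl) < min_inlier_ratio)
      stop(sprintf("registration failure: inlier ratio %.2f below floor %.2f",
                   mean(inl), min_inlier_ratio))
    list(pose = pose, inliers = inl, n_iter = it)
  })
}

refine_pose_from_subset <- function(K, pts3d, xn, pxu, mask) {
  S <- pts3d[mask, , drop = FALSE]
  sv <- svd(sweep(S, 2, colMeans(S)), nu = 0)
  init <- if (sv$d[3] < 0.05 * max(sv$d[1], 1e-12) || sum(mask) < 6) {
    pnp_planar(S, xn[mask, , drop = FALSE])
  } else {
    pnp_dlt(S, xn[mask, , drop = FALSE])
  }
  refine_pose(K, init, S, pxu[mask, , drop = FALSE])
}
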