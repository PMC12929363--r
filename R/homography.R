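# Planar homographies: the workhorse of floor-based calibration. A plane
# seen by two cameras induces an inter-image homography H ~ R + t n^T / d
# (normalized coordinates), which carries the relative pose that epipolar
# geometry cannot recover from coplanar points.

#' Normalize a homography matrix
#'
#' Fixed storage convention: unit Frobenius norm, sign chosen so the last
#' (3,3) element is positive (falling back to the last nonzero element when
#' it vanishes).
#'
#' @param H 3x3 nonsingular matrix.
#' @return 3x3 matrix in the declared normalization.
#' @export
normalize_homography <- function(H) {
  H <- as.matrix(H)
  stopifnot(all(dim(H) == c(3, 3)))
  nf <- sqrt(sum(H^2))
  if (nf < .Machine$double.eps) stop("invalid homography: zero matrix")
  H <- H / nf
  v <- as.numeric(H)[9:1]
  pivot <- v[which(abs(v) > 1e-14)[1]]
  if (is.na(pivot)) stop("invalid homography")
  if (pivot < 0) H <- -H
  H
}

#' Planar scaling transformation about a fixed point
#'
#' Returns the homography of the map `s(x) = lam * (x - p) + p`, the scaling
#' family used to build multi-scale markers: every member fixes the marker
#' center `p` exactly.
#'
#' @param p length-2 fixed point.
#' @param lam positive scale factor.
#' @return 3x3 homography matrix (affine; last row `(0, 0, 1)`).
#' @export
scaling_homography <- function(p, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || lam <= 0)
    stop("invalid scale: lam must be a positive scalar")
  matrix(c(lam, 0, 0,
           0, lam, 0,
           (1 - lam) * p[1], (1 - lam) * p[2], 1), 3, 3)
}

#' Apply a homography to 2D points
#'
#' @param H 3x3 homography.
#' @param x Nx2 matrix or length-2 vector.
#' @return transformed points, same shape as the input.
#' @export
apply_homography <- function(H, x) {
  single <- is.null(dim(x))
  x <- matrix(x, ncol = 2)
  Xh <- cbind(x, 1) %*% t(H)
  w <- Xh[, 3]
  if (any(abs(w) < 1e-300)) stop("point maps to the line at infinity")
  out <- Xh[, 1:2, drop = FALSE] / w
  if (single) as.numeric(out) else out
}

# Hartley-normalized DLT homography from >= 4 correspondences (Nx2, Nx2).
homography_dlt <- function(x1, x2) {
  n <- nrow(x1)
  stopifnot(n >= 4, nrow(x2) == n)
  norm_T <- function(x) {
    ctr <- colMeans(x)
    d <- sqrt(rowSums((x - matrix(ctr, n, 2, byrow = TRUE))^2))
    s <- sqrt(2) / max(mean(d), 1e-300)
    matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
  }
  T1 <- norm_T(x1); T2 <- norm_T(x2)
  a <- apply_homography(T1, x1); b <- apply_homography(T2, x2)
  A <- matrix(0, 2 * n, 9)
  u <- a[, 1]; v <- a[, 2]; up <- b[, 1]; vp <- b[, 2]
  o <- rep(1, n); z <- rep(0, n)
  A[seq(1, 2 * n, 2), ] <- cbind(z, z, z, -u, -v, -o, vp * u, vp * v, vp)
  A[seq(2, 2 * n, 2), ] <- cbind(u, v, o, z, z, z, -up * u, -up * v, -up)
  sv <- svd(A, nu = 0, nv = 9)
  h <- sv$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  if (abs(det(H)) < 1e-14) stop("degenerate configuration: singular homography fit")
  normalize_homography(solve(T2) %*% H %*% T1)
}

# any 3 of the 4 points collinear?
sample_degenerate <- function(x, tol = 1e-9) {
  idx <- utils::combn(nrow(x), 3)
  for (k in seq_len(ncol(idx))) {
    p <- x[idx[, k], ]
    a2 <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
              (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1]))
    scale <- max(abs(p)) + 1
    if (a2 < tol * scale^2) return(TRUE)
  }
  FALSE
}

#' Robust homography estimation with RANSAC
#'
#' Estimates the inter-image homography from 2D-2D correspondences given in
#' normalized camera coordinates. The pixel-domain inlier threshold
#' (default 3 px) is converted to the normalized domain per camera as
#' `threshold_px / sqrt(fx * fy)`, taking the more conservative (smaller) of
#' the two cameras. The inlier criterion is the one-sided transfer error in
#' the second image. Iteration count is adaptive at 0.999 confidence, capped
#' at 10000; the generator is seeded, so results are reproducible.
#'
#' @param x1,x2 Nx2 matrices of normalized coordinates (first/second view).
#' @param threshold_px RANSAC inlier threshold in pixels (default 3).
#' @param K1,K2 [camera_intrinsics()] of the two views (for the threshold
#'   conversion).
#' @param seed integer RNG seed.
#' @param max_iter iteration cap.
#' @return list with `H` (normalized per [normalize_homography()]),
#'   `inliers` (logical mask), `n_iter`.
#' @export
estimate_homography_ransac <- function(x1, x2, threshold_px = 3, K1, K2,
                                       seed = 1L, max_iter = 10000L) {
  x1 <- matrix(x1, ncol = 2); x2 <- matrix(x2, ncol = 2)
  n <- nrow(x1)
  if (n < 4) stop("insufficient data: need at least 4 correspondences")
  thr <- threshold_px / max(sqrt(K1$fx * K1$fy), sqrt(K2$fx * K2$fy))
  with_seed(seed, {
    best_inl <- NULL
    best_cnt <- -1L
    it <- 0L
    needed <- max_iter
    any_valid <- FALSE
    while (it < needed && it < max_iter) {
      it <- it + 1L
      idx <- sample.int(n, 4)
      if (sample_degenerate(x1[idx, , drop = FALSE]) ||
          sample_degenerate(x2[idx, , drop = FALSE])) next
      H <- tryCatch(homography_dlt(x1[idx, , drop = FALSE], x2[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H)) next
      any_valid <- TRUE
      e <- transfer_error(H, x1, x2)
      inl <- e < thr
      cnt <- sum(inl)
      if (cnt > best_cnt) {
        best_cnt <- cnt
        best_inl <- inl
        needed <- ransac_iterations(cnt / n, 4L, max_iter)
      }
    }
    if (!any_valid) stop("degenerate configuration: all minimal samples degenerate")
    if (best_cnt < 4) stop("degenerate configuration: no homography supports 4 inliers")
    # refit on all inliers by normalized DLT, then refresh the mask once
    H <- homography_dlt(x1[best_inl, , drop = FALSE], x2[best_inl, , drop = FALSE])
    inl <- transfer_error(H, x1, x2) < thr
    if (sum(inl) >= 4)
      H <- homography_dlt(x1[inl, , drop = FALSE], x2[inl, , drop = FALSE])
    else inl <- best_inl
    list(H = normalize_homography(H), inliers = inl, n_iter = it)
  })
}

# adaptive RANSAC iteration count at 0.999 confidence; guards against the
# log(1 - w^k) underflow when the inlier ratio w is (near) zero
ransac_iterations <- function(w, sample_size, max_iter, confidence = 0.999) {
  p_good <- w^sample_size
  if (!is.finite(p_good) || p_good < 1e-12) return(max_iter)
  if (p_good >= 1) return(1L)
  min(max_iter, ceiling(log(1 - confidence) / log(1 - p_good)))
}

# one-sided transfer error in the second image
transfer_error <- function(H, x1, x2) {
  Xh <- cbind(x1, 1) %*% t(H)
  w <- Xh[, 3]
  bad <- abs(w) < 1e-12
  w[bad] <- 1
  e <- sqrt((Xh[, 1] / w - x2[, 1])^2 + (Xh[, 2] / w - x2[, 2])^2)
  e[bad] <- Inf
  e
}

#' Decompose a plane-induced homography
#'
#' Analytic decomposition of a homography between two calibrated views of a
#' plane into the up-to-four physical solutions `(R, t/d, n)` with the plane
#' at positive distance, following the classical SVD construction. `H` must
#' be expressed in normalized (intrinsics-removed) coordinates and satisfies
#' `H ~ R + (t/d) n^T` for each returned candidate.
#'
#' @param H 3x3 homography in normalized coordinates.
#' @return list of candidates, each a list with `R` (rotation), `t`
#'   (translation scaled by the inverse plane distance, i.e. t/d), and `n`
#'   (unit plane normal in the first camera frame).
#' @export
decompose_homography <- function(H) {
  H <- as.matrix(H)
  if (abs(det(H)) < 1e-14) stop("invalid homography: singular matrix")
  sv <- svd(H)
  d1 <- sv$d[1]; d2 <- sv$d[2]; d3 <- sv$d[3]
  U <- sv$u; V <- sv$v
  s <- det(U) * det(V)
  # scale so the middle singular value is 1
  if (d2 < 1e-14) stop("invalid homography: rank deficient")
  d1 <- d1 / d2; d3 <- d3 / d2
  out <- list()
  if (d1 - d3 < 1e-9) {
    # pure rotation (all singular values equal): H ~ R, plane at infinity
    R <- closest_rotation(H * sign(det(H)))
    return(list(list(R = R, t = c(0, 0, 0), n = c(0, 0, 1))))
  }
  x1m <- sqrt(max((d1^2 - 1) / (d1^2 - d3^2), 0))
  x3m <- sqrt(max((1 - d3^2) / (d1^2 - d3^2), 0))
  for (e1 in c(1, -1)) for (e3 in c(1, -1)) {
    x1 <- e1 * x1m; x3 <- e3 * x3m
    st <- (d1 - d3) * x1 * x3
    ct <- d1 * x3^2 + d3 * x1^2
    Rp <- matrix(c(ct, 0, st,
                   0, 1, 0,
                   -st, 0, ct), 3, 3)
    tp <- (d1 - d3) * c(x1, 0, -x3)
    np <- c(x1, 0, x3)
    R <- s * U %*% Rp %*% t(V)
    n <- as.numeric(V %*% np)
    t <- as.numeric(U %*% tp)
    # orient the plane normal toward the first camera (n^T X = d > 0 for
    # points in front, normal pointing at the camera means n_z < 0 ... we
    # adopt n such that the plane is at +d along n from the origin); flip
    # both n and t together if needed so that d > 0 with n pointing away
    # from camera one's center along the viewing direction.
    if (n[3] < 0) { n <- -n; t <- -t }
    out[[length(out) + 1]] <- list(R = R, t = t, n = n)
  }
  # deduplicate (pairs coincide when x1m or x3m is 0)
  uniq <- list()
  for (cand in out) {
    dup <- FALSE
    for (u in uniq) {
      if (max(abs(u$R - cand$R)) < 1e-9 && max(abs(u$t - cand$t)) < 1e-9 &&
          max(abs(u$n - cand$n)) < 1e-9) { dup <- TRUE; break }
    }
    if (!dup) uniq[[length(uniq) + 1]] <- cand
  }
  uniq
}

#' Select the physical homography decomposition
#'
#' Disambiguates the analytic candidates by cheirality: triangulates the
#' correspondences under each candidate (with `t` rescaled to unit norm) and
#' keeps the candidate with the largest fraction of points with positive
#' depth in both views and the plane normal facing the first camera. When
#' both remaining solutions pass every physical constraint -- the classical
#' two-fold ambiguity of plane-induced homographies -- the tie is resolved
#' by an upright-camera prior: for roll-free cameras observing a floor the
#' floor normal lies in the camera's y-z plane, so the candidate with the
#' smaller |n_x| is preferred, then the normal best aligned with the mean
#' observed ray, then the lower mean transfer error.
#'
#' @param candidates list from [decompose_homography()].
#' @param x1,x2 Nx2 normalized correspondences.
#' @return list with `R`, `t` (unit norm, or zero for no-motion), `n`.
#' @export
select_decomposition <- function(candidates, x1, x2) {
  x1 <- matrix(x1, ncol = 2); x2 <- matrix(x2, ncol = 2)
  stopifnot(length(candidates) >= 1, nrow(x1) >= 2)
  if (nrow(x1) > 200) {
    keep <- unique(round(seq(1, nrow(x1), length.out = 200)))
    x1 <- x1[keep, , drop = FALSE]; x2 <- x2[keep, , drop = FALSE]
  }
  if (length(candidates) == 1) {
    cand <- candidates[[1]]
    tn <- if (vnorm(cand$t) > 1e-12) unit(cand$t) else cand$t * 0
    return(list(R = cand$R, t = tn, n = cand$n))
  }
  rays <- cbind(x1, 1)
  rays <- rays / sqrt(rowSums(rays^2))
  mean_ray <- colMeans(rays)
  mean_ray <- mean_ray / vnorm(mean_ray)
  best <- NULL; best_frac <- -1; best_upright <- -Inf
  best_align <- -Inf; best_err <- Inf
  for (cand in candidates) {
    tn <- if (vnorm(cand$t) > 1e-12) unit(cand$t) else cand$t * 0
    P1 <- camera_pose()
    P2 <- camera_pose(closest_rotation(cand$R), tn)
    z1 <- z2 <- numeric(nrow(x1))
    for (i in seq_len(nrow(x1))) {
      X <- tryCatch(triangulate_linear(list(P1, P2), rbind(x1[i, ], x2[i, ])),
                    error = function(e) c(NA, NA, NA))
      if (anyNA(X)) { z1[i] <- z2[i] <- -1; next }
      z1[i] <- X[3]
      z2[i] <- (P2$R %*% X + P2$t)[3]
    }
    frac <- mean(z1 > 0 & z2 > 0)
    # plane normal must face the first camera: points X on the plane have
    # n . X = d > 0 and sit in front (z > 0), so require n_z > 0 and every
    # observed ray to intersect the candidate plane at positive depth
    # (n . ray > 0); the second camera must sit on the same side of the
    # plane as the first (d2/d = 1 + n' R' t > 0)
    if (cand$n[3] < 0) frac <- frac - 1
    if (min(rays %*% cand$n) <= 0) frac <- frac - 1
    if (1 + sum(cand$n * crossprod(cand$R, cand$t)) <= 0) frac <- frac - 1
    Hc <- cand$R + cand$t %*% t(cand$n)
    err <- mean(pmin(transfer_error(Hc, x1, x2), 1e6))
    align <- sum(cand$n * mean_ray)
    upright <- -abs(cand$n[1])
    better <- frac > best_frac + 1e-9 ||
      (abs(frac - best_frac) <= 1e-9 &&
         (upright > best_upright + 1e-9 ||
            (abs(upright - best_upright) <= 1e-9 &&
               (align > best_align + 1e-9 ||
                  (abs(align - best_align) <= 1e-9 && err < best_err)))))
    if (better) {
      best <- list(R = closest_rotation(cand$R), t = tn, n = cand$n)
      best_frac <- frac; best_upright <- upright
      best_align <- align; best_err <- err
    }
  }
  if (best_frac <= 0.5)
    stop("decomposition failure: no candidate passes cheirality for a majority of points")
  best
}
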