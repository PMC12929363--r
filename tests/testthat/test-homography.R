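# Robust homography estimation and plane-induced decomposition.

test_that("RANSAC recovers a known homography from noiseless correspondences", {
  set.seed(31)
  H <- matrix(c(0.9, 0.05, 0.01, -0.04, 1.1, 0.02, 0.003, -0.001, 1), 3, 3)
  x1 <- cbind(runif(20, -0.5, 0.5), runif(20, -0.5, 0.5))
  x2 <- apply_homography(H, x1)
  K <- hd_intrinsics()
  res <- estimate_homography_ransac(x1, x2, 3, K, K, seed = 5)
  expect_true(all(res$inliers))
  Hn <- normalize_homography(H)
  expect_lt(max(abs(res$H - Hn)), 1e-8)
})

test_that("RANSAC isolates exactly the true inliers under 30% gross outliers", {
  set.seed(32)
  H <- matrix(c(1.05, 0.02, 0, 0.01, 0.95, 0.03, 0.002, 0.001, 1), 3, 3)
  x1 <- cbind(runif(20, -0.5, 0.5), runif(20, -0.5, 0.5))
  x2 <- apply_homography(H, x1)
  out_idx <- 15:20   # 6 of 20 corrupted
  x2[out_idx, ] <- cbind(runif(6, -0.5, 0.5), runif(6, -0.5, 0.5)) + 0.3
  K <- hd_intrinsics()
  res <- estimate_homography_ransac(x1, x2, 3, K, K, seed = 8)
  expect_equal(which(res$inliers), 1:14)
})

test_that("RANSAC rejects degenerate minimal configurations and inputs", {
  x1 <- rbind(c(0, 0), c(1, 0), c(2, 0), c(0.5, 1))  # 3 collinear sources
  x2 <- x1 + 0.01
  K <- hd_intrinsics()
  expect_error(estimate_homography_ransac(x1, x2, 3, K, K, seed = 1),
               "degenerate")
  expect_error(estimate_homography_ransac(x1[1:3, ], x2[1:3, ], 3, K, K, seed = 1),
               "insufficient")
})

test_that("RANSAC with a fixed seed is bit-reproducible", {
  set.seed(33)
  sc <- coplanar_two_view(n = 200)
  K <- hd_intrinsics()
  x1 <- pixel_to_normalized(K, project_point(K, sc$P1, sc$X))
  x2 <- pixel_to_normalized(K, project_point(K, sc$P2, sc$X))
  x2 <- x2 + rnorm(length(x2), 0, 2e-4)
  a <- estimate_homography_ransac(x1, x2, 3, K, K, seed = 99)
  b <- estimate_homography_ransac(x1, x2, 3, K, K, seed = 99)
  expect_identical(a, b)
})

test_that("homography normalization convention is unit-Frobenius with positive pivot", {
  set.seed(34)
  for (i in 1:20) {
    H <- matrix(rnorm(9), 3, 3)
    if (abs(det(H)) < 1e-3) next
    Hn <- normalize_homography(H)
    expect_equal(sqrt(sum(Hn^2)), 1, tolerance = 1e-12)
    expect_gt(Hn[3, 3], 0)
    expect_equal(normalize_homography(-3.7 * H), Hn, tolerance = 1e-12)
  }
})

test_that("decomposition candidates reproduce H and contain the generating motion", {
  set.seed(35)
  for (i in 1:100) {
    gtr <- random_plane_homography()
    cands <- decompose_homography(gtr$H)
    # every candidate reconstructs H up to scale
    Hn <- normalize_homography(gtr$H)
    for (cc in cands) {
      Hc <- normalize_homography(cc$R + cc$t %*% t(cc$n))
      expect_lt(max(abs(Hc - Hn)), 1e-8)
    }
    best <- min(vapply(cands, function(cc)
      max(rotation_angle(cc$R, gtr$R),
          sqrt(sum((unit_or_zero(cc$t) - unit_or_zero(gtr$t))^2))), numeric(1)))
    expect_lt(best, 1e-6)
  }
})

test_that("identity and pure-rotation homographies decompose to zero translation", {
  cands <- decompose_homography(diag(3))
  expect_length(cands, 1)
  expect_equal(cands[[1]]$R, diag(3), tolerance = 1e-10)
  expect_equal(sqrt(sum(cands[[1]]$t^2)), 0, tolerance = 1e-10)
  set.seed(36)
  R <- random_rotation()
  cands <- decompose_homography(R)
  expect_equal(cands[[1]]$R, R, tolerance = 1e-9)
  expect_equal(sqrt(sum(cands[[1]]$t^2)), 0, tolerance = 1e-10)
  expect_error(decompose_homography(matrix(0, 3, 3)), "invalid homography")
})

test_that("cheirality-based selection returns the generating two-view pose", {
  set.seed(37)
  K <- hd_intrinsics()
  for (i in 1:100) {
    sc <- coplanar_two_view(n = 40, az = sort(runif(2, 0, 2 * pi)),
                            radius = runif(1, 2, 3), height = runif(1, 2, 3))
    Prel <- msmcalib:::relative_pose(sc$P1, sc$P2)
    x1 <- pixel_to_normalized(K, project_point(K, sc$P1, sc$X))
    x2 <- pixel_to_normalized(K, project_point(K, sc$P2, sc$X))
    H <- msmcalib:::homography_dlt(x1, x2)
    sel <- select_decomposition(decompose_homography(H), x1, x2)
    expect_lt(rotation_angle(sel$R, Prel$R), 1e-6)
    expect_lt(max(abs(sel$t - unit_or_zero(Prel$t))), 1e-6)
  }
})

test_that("selection passes a singleton through and fails on mirror scenes", {
  set.seed(38)
  cand <- list(list(R = diag(3), t = c(1, 0, 0), n = c(0, 0, 1)))
  sel <- select_decomposition(cand, cbind(c(0, 0.1), c(0, 0)), cbind(c(0.1, 0.2), c(0, 0)))
  expect_equal(sel$R, diag(3))
  expect_equal(sel$t, c(1, 0, 0))
  # mirror scene: correspondences consistent only with points behind both
  # cameras, so every candidate fails cheirality
  ab <- cbind(runif(30, -0.6, 0.6), runif(30, -0.6, 0.6))
  Xb <- cbind(ab, -2)                      # z = -2, behind camera one
  x1 <- Xb[, 1:2] / Xb[, 3]
  x2 <- cbind(ab[, 1] / -1, ab[, 2] / -1)  # second camera at t = (0,0,1)
  cands <- list(list(R = diag(3), t = c(0, 0, 1), n = c(0, 0, 1)),
                list(R = diag(3), t = c(0, 0, 0.5), n = c(0, 0, 1)))
  expect_error(select_decomposition(cands, x1, x2), "decomposition failure")
})
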