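# Camera model, projection and distortion.

test_that("pinhole projection matches hand-computed cases", {
  K <- camera_intrinsics(1000, 1000, 500, 500, width = 1000, height = 1000)
  P <- camera_pose()
  expect_equal(project_point(K, P, c(0, 0, 1)), c(500, 500), tolerance = 1e-12)
  expect_equal(project_point(K, P, c(0.1, 0, 1)), c(600, 500), tolerance = 1e-12)
  expect_error(project_point(K, P, c(0, 0, -1)), "cheirality")
  expect_error(project_point(K, P, c(0, 0, 0)), "cheirality")
})

test_that("full projection equals an independently composed transform-normalize-distort chain", {
  set.seed(101)
  K <- camera_intrinsics(880, 905, 940, 560, dist = c(-0.21, 0.04, 0.0011, -0.0007, 0.01),
                         width = 1920, height = 1080, camera_id = "d")
  for (rep in 1:20) {
    R <- random_rotation()
    P <- camera_pose(R, c(rnorm(2, 0, 0.2), runif(1, 2, 4)))
    X <- c(rnorm(2, 0, 0.3), runif(1, 2, 4))
    Xc <- as.numeric(R %*% X + P$t)
    if (Xc[3] <= 0.1) next
    xn <- Xc[1:2] / Xc[3]
    r2 <- sum(xn^2); d <- K$dist
    rad <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
    xd <- c(xn[1] * rad + 2 * d[3] * xn[1] * xn[2] + d[4] * (r2 + 2 * xn[1]^2),
            xn[2] * rad + d[3] * (r2 + 2 * xn[2]^2) + 2 * d[4] * xn[1] * xn[2])
    expected <- c(xd[1] * K$fx + K$cx, xd[2] * K$fy + K$cy)
    expect_equal(project_point(K, P, X), expected, tolerance = 1e-9)
  }
})

test_that("distortion round-trips to 1e-8 px for in-image points", {
  set.seed(7)
  K <- camera_intrinsics(900, 910, 960, 540, dist = c(-0.2, 0.05, 0.001, -0.002, 0.008),
                         width = 1920, height = 1080)
  px <- cbind(runif(200, 0, 1919), runif(200, 0, 1079))
  back <- normalized_to_pixel(K, pixel_to_normalized(K, px), distorted = TRUE)
  expect_lt(max(abs(back - px)), 1e-8)
  # undistorted projection equals ideal pinhole on the normalized point
  xn <- pixel_to_normalized(K, px)
  ideal <- cbind(xn[, 1] * K$fx + K$cx, xn[, 2] * K$fy + K$cy)
  expect_equal(undistort_pixels(K, px), ideal, tolerance = 1e-8)
})

test_that("intrinsics and pose constructors enforce their invariants", {
  expect_error(camera_intrinsics(-1, 900, 960, 540, width = 1920, height = 1080),
               "positive")
  expect_error(camera_intrinsics(900, 900, 2000, 540, width = 1920, height = 1080),
               "principal point")
  expect_error(camera_pose(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
  M <- diag(c(1, 1, -1))  # improper
  expect_error(camera_pose(M, c(0, 0, 0)), "orthonormal")
})

test_that("look-at poses aim the optical axis exactly at the target", {
  set.seed(21)
  for (i in 1:20) {
    ctr <- c(rnorm(2, 0, 3), runif(1, 0.5, 4))
    P <- look_at_pose(ctr, c(0, 0, 0))
    dir <- as.numeric(t(P$R) %*% c(0, 0, 1))   # optical axis in world coords
    expect_equal(sum(dir * (-ctr) / sqrt(sum(ctr^2))), 1, tolerance = 1e-12)
    expect_equal(pose_center(P), ctr, tolerance = 1e-12)
  }
})

test_that("scaling homographies fix their center and scale as stated", {
  expect_equal(scaling_homography(c(3, -2), 1), diag(3))
  for (lam in c(0.5, 2, 8)) {
    p <- c(12.3, -4.5)
    S <- scaling_homography(p, lam)
    expect_equal(apply_homography(S, p), p, tolerance = 1e-14)
  }
  expect_equal(apply_homography(scaling_homography(c(0, 0), 2), c(1, 1)),
               c(2, 2), tolerance = 1e-14)
  expect_error(scaling_homography(c(0, 0), 0), "invalid scale")
  expect_error(scaling_homography(c(0, 0), -1), "invalid scale")
})
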