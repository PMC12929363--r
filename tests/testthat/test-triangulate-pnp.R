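# Multi-view triangulation and robust camera resectioning.

test_that("triangulation recovers a known point and is consistent across view counts", {
  set.seed(41)
  K <- hd_intrinsics()
  poses <- lapply(1:6, function(i)
    look_at_pose(c(2.8 * cos(i), 2.8 * sin(i), 2.8), c(0, 0, 0)))
  X <- c(0.4, -0.2, 0.1)
  obs <- t(vapply(poses, function(P) project_point(K, P, X), numeric(2)))
  Ks <- rep(list(K), 6)
  X2 <- triangulate_point(poses[1:2], Ks[1:2], obs[1:2, ])
  expect_lt(sqrt(sum((X2 - X)^2)), 1e-8)
  X6 <- triangulate_point(poses, Ks, obs)
  expect_lt(sqrt(sum((X6 - X2)^2)), 1e-8)
})

test_that("triangulation signals zero baseline and cheirality failures", {
  K <- hd_intrinsics()
  P <- look_at_pose(c(2, 0, 2), c(0, 0, 0))
  expect_error(triangulate_point(list(P, P), list(K, K),
                                 rbind(c(900, 500), c(905, 500))),
               "zero baseline")
})

test_that("PnP recovers a pose from a noiseless 3D grid and from coplanar floor points", {
  set.seed(42)
  K <- hd_intrinsics()
  P <- look_at_pose(c(1.8, -1.2, 2.4), c(0, 0, 0))
  g <- expand.grid(x = seq(-1, 1, length.out = 5), y = seq(-1, 1, length.out = 4),
                   z = c(0, 0.4, 0.9))
  X3 <- as.matrix(g)
  px <- project_point(K, P, X3)
  r3 <- pnp_ransac(K, X3, px, seed = 4)
  expect_lt(rotation_angle(r3$pose$R, P$R), 1e-6)
  expect_lt(max(abs(r3$pose$t - P$t)), 1e-6)
  expect_true(all(r3$inliers))
  # planar configuration exercises the homography-based minimal path
  Xf <- cbind(runif(60, -1.2, 1.2), runif(60, -1.2, 1.2), 0)
  pxf <- project_point(K, P, Xf)
  rf <- pnp_ransac(K, Xf, pxf, seed = 4)
  expect_lt(rotation_angle(rf$pose$R, P$R), 1e-6)
  expect_lt(max(abs(rf$pose$t - P$t)), 1e-6)
})

test_that("PnP excludes a gross outlier from the inlier mask", {
  set.seed(43)
  K <- hd_intrinsics()
  P <- look_at_pose(c(1.5, 0.8, 2.2), c(0, 0, 0))
  X <- cbind(runif(20, -1, 1), runif(20, -1, 1), 0)
  px <- project_point(K, P, X)
  px[7, ] <- px[7, ] + c(180, -140)
  res <- pnp_ransac(K, X, px, seed = 9)
  expect_false(res$inliers[7])
  expect_equal(sum(res$inliers), 19)
  expect_error(pnp_ransac(K, X[1:3, ], px[1:3, ], seed = 1), "insufficient")
})
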