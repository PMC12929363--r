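# View scoring, incremental registration and bundle adjustment.

test_that("the multi-level occupancy score follows its defining formula", {
  expect_equal(view_score(matrix(numeric(), 0, 2), 1920, 1080), 0)
  expect_equal(view_score(c(10, 10), 1920, 1080, levels = 2), 2 + 4)
  expect_equal(view_score(c(10, 10), 1920, 1080, levels = 6), sum(2^(1:6)))
  set.seed(81)
  spread <- cbind(runif(100, 0, 1919), runif(100, 0, 1079))
  clustered <- cbind(runif(100, 0, 20), runif(100, 0, 20))
  expect_gt(view_score(spread, 1920, 1080), view_score(clustered, 1920, 1080))
  # adding a correspondence never decreases the score
  s0 <- view_score(spread[1:50, ], 1920, 1080)
  s1 <- view_score(spread[1:51, ], 1920, 1080)
  expect_gte(s1, s0)
})

test_that("initial-pair selection prefers well-spread shared correspondences", {
  set.seed(82)
  sc <- small_rig_tracks(n_cam = 2, nx = 12, ny = 8)
  expect_equal(sort(select_initial_pair(sc$tracks, sc$intrinsics)),
               c("cam01", "cam02"))
  # camera 3 shares only 10 clustered points with camera 1
  obs <- sc$tracks$observations
  few <- obs[obs$camera_id == "cam01", ][1:10, ]
  few$camera_id <- "cam03"
  tr <- build_tracks(rbind(obs, few))
  K3 <- c(sc$intrinsics, list(cam03 = sc$intrinsics[[1]]))
  expect_equal(sort(select_initial_pair(tr, K3, min_shared = 5)),
               c("cam01", "cam02"))
  # deterministic under fixed input
  expect_identical(select_initial_pair(tr, K3, min_shared = 5),
                   select_initial_pair(tr, K3, min_shared = 5))
  expect_error(select_initial_pair(sc$tracks, sc$intrinsics, min_shared = 1e6),
               "cannot start")
})

test_that("pair initialization recovers the relative motion of a floor-point pair", {
  set.seed(83)
  sc <- small_rig_tracks(n_cam = 2, nx = 20, ny = 10)
  rec <- initialize_pair("cam01", "cam02", sc$tracks, sc$intrinsics,
                         list(seed = 5))
  Prel <- msmcalib:::relative_pose(sc$poses$cam01, sc$poses$cam02)
  expect_lt(rotation_angle(rec$poses$cam02$R, Prel$R), 1e-6)
  expect_lt(max(abs(rec$poses$cam02$t - unit_or_zero(Prel$t))), 1e-6)
  expect_gt(nrow(rec$points), 100)
})

test_that("pair initialization under 1 px noise stays within 0.2 degrees", {
  set.seed(84)
  # floor field matching the projected-marker footprint (~4 x 2.4 m)
  sc <- small_rig_tracks(n_cam = 2, nx = 50, ny = 40, sigma = 1,
                         extent = c(2, 1.2))
  rec <- initialize_pair("cam01", "cam02", sc$tracks, sc$intrinsics,
                         list(seed = 5))
  Prel <- msmcalib:::relative_pose(sc$poses$cam01, sc$poses$cam02)
  expect_lt(rot_geodesic_deg(rec$poses$cam02$R, Prel$R), 0.2)
})

test_that("a pure-rotation pair fails initialization", {
  set.seed(85)
  K <- hd_intrinsics()
  ctr <- c(2, 1, 2.5)
  P1 <- look_at_pose(ctr, c(0, 0, 0))
  P2 <- look_at_pose(ctr, c(0.4, 0.2, 0))   # same center, rotated
  X <- cbind(runif(100, -1, 1), runif(100, -1, 1), 0)
  obs <- rbind(
    data.frame(camera_id = "a", marker_id = 1:100,
               x = project_point(K, P1, X)[, 1], y = project_point(K, P1, X)[, 2]),
    data.frame(camera_id = "b", marker_id = 1:100,
               x = project_point(K, P2, X)[, 1], y = project_point(K, P2, X)[, 2]))
  tr <- build_tracks(obs)
  Ks <- list(a = K, b = K)
  expect_error(initialize_pair("a", "b", tr, Ks, list(seed = 2)),
               "initialization error")
})

test_that("bundle adjustment is a fixed point at ground truth and strictly descends", {
  set.seed(86)
  sc <- small_rig_tracks(n_cam = 5, nx = 16, ny = 10)
  rec <- initialize_pair("cam01", "cam02", sc$tracks, sc$intrinsics,
                         list(seed = 5))
  while (!is.null(attr(rec <- register_next(rec), "registered"))) {}
  # exact data: BA objective is ~0 and parameters do not move
  poses_before <- rec$poses
  rec2 <- bundle_adjust(rec)
  expect_lt(attr(rec2, "ba_objective"), 1e-12)
  for (cid in rec$registered) {
    # acos() noise floor is ~2e-8 rad for identical rotations
    expect_lt(rotation_angle(rec2$poses[[cid]]$R, poses_before[[cid]]$R), 1e-6)
    expect_lt(max(abs(rec2$poses[[cid]]$t - poses_before[[cid]]$t)), 1e-8)
  }
  # perturb away from the optimum: BA recovers and never increases the objective
  rec3 <- rec2
  for (cid in rec3$registered[3:5]) {
    rec3$poses[[cid]] <- camera_pose(
      rot_from_rotvec(c(0.5, 0, 0) * pi / 180) %*% rec3$poses[[cid]]$R,
      rec3$poses[[cid]]$t + c(0.05, 0, 0) * 0.3)  # ~0.5 deg / scaled 5 cm
  }
  r3 <- msmcalib:::reconstruction_residuals(rec3)
  obj_before <- sum(r3$enorm^2)
  rec4 <- bundle_adjust(rec3)
  expect_lt(attr(rec4, "ba_objective"), 1e-6)
  expect_lt(attr(rec4, "ba_objective"), obj_before)
})

test_that("incremental registration handles full rigs and disconnected cameras", {
  set.seed(87)
  sc <- small_rig_tracks(n_cam = 6, nx = 16, ny = 10)
  fit <- calibrate(sc$tracks, sc$intrinsics, options = list(seed = 7))
  expect_length(fit$registered, 6)
  expect_length(fit$unregistered, 0)
  # a camera sharing no tracks is reported unregistered, no exception
  obs <- sc$tracks$observations
  lone <- data.frame(camera_id = "lone", marker_id = 9001:9012,
                     x = runif(12, 0, 1919), y = runif(12, 0, 1079))
  tr <- build_tracks(rbind(obs, lone))
  Ks <- c(sc$intrinsics, list(lone = hd_intrinsics(id = "lone")))
  fit2 <- calibrate(tr, Ks, options = list(seed = 7))
  expect_equal(fit2$unregistered, "lone")
  expect_length(fit2$registered, 6)
})

test_that("zero-noise calibration is exact and the coplanar variant flattens the points", {
  set.seed(88)
  sc <- small_rig_tracks(n_cam = 6, nx = 20, ny = 12)
  fit <- calibrate(sc$tracks, sc$intrinsics, options = list(seed = 3))
  pe <- pose_error(fit$poses, sc$poses)
  expect_lt(pe$rotation_rmse_deg, 1e-5)
  expect_lt(pe$translation_rmse_m, 1e-5)
  fitc <- calibrate(sc$tracks, sc$intrinsics,
                    options = list(seed = 3, coplanar = TRUE))
  expect_length(fitc$registered, 6)
  X <- as.matrix(fitc$points[, c("X", "Y", "Z")])
  z_spread <- svd(sweep(X, 2, colMeans(X)), nu = 0)$d[3]
  expect_lt(z_spread, 1e-9)
  expect_true(all(fitc$points$on_floor))
  pec <- pose_error(fitc$poses, sc$poses)
  expect_lt(pec$rotation_rmse_deg, 1e-5)
})

test_that("residuals under noise match the chi-square expectation within 20%", {
  set.seed(89)
  sigma <- 0.5
  sc <- small_rig_tracks(n_cam = 6, nx = 20, ny = 12, sigma = sigma)
  fit <- calibrate(sc$tracks, sc$intrinsics,
                   options = list(seed = 3, outlier_sigmas = 1e6))
  n_obs <- nrow(fit$residuals)
  n_pts <- nrow(fit$points)
  # E[sum of squared residuals] = sigma^2 (2 N - P) at the LS optimum
  P <- 6 * (length(fit$registered) - 1) - 1 + 3 * n_pts
  expected_rms <- sigma * sqrt((2 * n_obs - P) / n_obs)
  rms <- sqrt(mean(fit$residuals$enorm^2))
  expect_lt(abs(rms - expected_rms) / expected_rms, 0.2)
})

test_that("calibration is invariant to the world frame used for the inputs (gauge)", {
  set.seed(90)
  sc <- small_rig_tracks(n_cam = 4, nx = 16, ny = 10)
  fit1 <- calibrate(sc$tracks, sc$intrinsics, options = list(seed = 11))
  # re-express the same scene in a rotated/translated world frame
  Rw <- random_rotation(); tw <- c(1.5, -0.7, 0.3)
  poses2 <- lapply(sc$poses, function(P)
    camera_pose(P$R %*% t(Rw), as.numeric(P$t - P$R %*% t(Rw) %*% tw)))
  X2 <- sc$X %*% t(Rw) + matrix(tw, nrow(sc$X), 3, byrow = TRUE)
  K <- sc$intrinsics[[1]]
  obs2 <- do.call(rbind, lapply(names(poses2), function(cid) {
    px <- project_point(K, poses2[[cid]], X2)
    data.frame(camera_id = cid, marker_id = seq_len(nrow(X2)) - 1L,
               x = px[, 1], y = px[, 2])
  }))
  fit2 <- calibrate(build_tracks(obs2), sc$intrinsics, options = list(seed = 11))
  pe <- pose_error(fit1$poses, fit2$poses)
  expect_lt(pe$rotation_rmse_deg, 1e-5)
  expect_lt(pe$translation_rmse_m, 1e-6)
})

test_that("repeated runs with one seed write byte-identical pose files", {
  set.seed(91)
  sc <- small_rig_tracks(n_cam = 4, nx = 16, ny = 10, sigma = 0.3)
  f1 <- tempfile(); f2 <- tempfile()
  fit1 <- calibrate(sc$tracks, sc$intrinsics, options = list(seed = 17))
  fit2 <- calibrate(sc$tracks, sc$intrinsics, options = list(seed = 17))
  save_poses(fit1$poses, f1, seed = 17)
  save_poses(fit2$poses, f2, seed = 17)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})
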