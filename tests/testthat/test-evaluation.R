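# Pose-error metrics, held-out evaluation protocol and point-cloud
# comparison.

test_that("pose error vanishes for identical poses and for gauge-transformed copies", {
  set.seed(101)
  poses <- lapply(1:6, function(i)
    look_at_pose(c(2.8 * cos(i), 2.8 * sin(i), 2.8), c(0, 0, 0)))
  names(poses) <- sprintf("c%d", 1:6)
  pe <- pose_error(poses, poses)
  # acos() near 1 amplifies machine noise; identical poses stay below 1e-5 deg
  expect_lt(pe$rotation_rmse_deg, 1e-5)
  expect_lt(pe$translation_rmse_m, 1e-9)
  # a global Sim(3) of the world is removed by the alignment
  S <- list(s = 1.7, R = random_rotation(), t = c(0.3, -0.8, 0.5))
  moved <- lapply(poses, msmcalib:::transform_pose_sim3, S)
  pe2 <- pose_error(moved, poses)
  expect_lt(pe2$rotation_rmse_deg, 1e-6)
  expect_lt(pe2$translation_rmse_m, 1e-9)
  expect_error(pose_error(poses[1:2], poses[1:2]), "fewer than 3")
})

test_that("a single 1-degree rotation yields RMSE 1/sqrt(n) degrees", {
  set.seed(102)
  poses <- lapply(1:9, function(i)
    look_at_pose(c(2.8 * cos(0.7 * i), 2.8 * sin(0.7 * i), 2.8), c(0, 0, 0)))
  names(poses) <- sprintf("c%d", 1:9)
  est <- poses
  # rotate camera 4 about its own center so the center cloud (and thus the
  # Sim(3) alignment) is untouched
  ctr <- pose_center(est$c4)
  Rn <- rot_from_rotvec(c(pi / 180, 0, 0)) %*% est$c4$R
  est$c4 <- camera_pose(Rn, as.numeric(-Rn %*% ctr))
  pe <- pose_error(est, poses)
  expect_equal(pe$rotation_rmse_deg, 1 / sqrt(9), tolerance = 1e-6)
  expect_lt(pe$translation_rmse_m, 1e-9)
})

test_that("success rates count cameras below each threshold, monotonically", {
  r <- success_rates(c(0.4, 1.5, 4.9), c(0.5, 2, 5))
  expect_equal(as.numeric(r), c(100 / 3, 200 / 3, 100), tolerance = 1e-9)
  expect_equal(success_rates(c(Inf, 0.1), c(0.5, 2, 5)), c(50, 50, 50))
  set.seed(103)
  e <- abs(rnorm(20, 1, 1))
  expect_true(all(diff(success_rates(e, c(0.5, 2, 5))) >= 0))
})

test_that("held-out evaluation is self-consistent and refinement never hurts", {
  set.seed(104)
  sc <- small_rig_tracks(n_cam = 5, nx = 10, ny = 6)
  rep <- evaluate_on_heldout(sc$poses, sc$intrinsics, sc$tracks)
  expect_equal(as.numeric(rep$rates), c(100, 100, 100))
  expect_lt(max(rep$per_camera$mean_reproj_px), 1e-6)
  # recovered points equal the generating floor points
  m <- match(rep$points$marker_id, seq_len(nrow(sc$X)) - 1L)
  expect_lt(max(abs(as.matrix(rep$points[, c("X", "Y", "Z")]) - sc$X[m, ])), 1e-6)
  # a camera without a pose fails every threshold
  rep2 <- evaluate_on_heldout(sc$poses[1:4], sc$intrinsics, sc$tracks)
  expect_equal(as.numeric(rep2$rates), c(80, 80, 80))
})

test_that("point-cloud comparison matches a Monte-Carlo error oracle", {
  set.seed(105)
  n <- 4000
  A <- data.frame(marker_id = 1:n, X = runif(n, -2, 2), Y = runif(n, -2, 2),
                  Z = runif(n, 0, 1))
  expect_equal(compare_point_clouds(A, A)$mean_error, 0, tolerance = 1e-12)
  sigma <- 0.001
  B <- A
  B[, c("X", "Y", "Z")] <- B[, c("X", "Y", "Z")] + matrix(rnorm(3 * n, 0, sigma), n, 3)
  cc <- compare_point_clouds(A, B)
  # chi distribution with 3 dof: mean = sigma * sqrt(2) * gamma(2) / gamma(1.5)
  expected <- sigma * sqrt(2) * gamma(2) / gamma(1.5)
  expect_lt(abs(cc$mean_error - expected) / expected, 0.05)
  # alignment removes an injected global similarity exactly
  S <- list(s = 0.6, R = random_rotation(), t = c(1, 2, 3))
  C <- A
  C[, c("X", "Y", "Z")] <- apply_sim3(structure(S, class = "sim3"),
                                      as.matrix(A[, c("X", "Y", "Z")]))
  expect_lt(compare_point_clouds(A, C)$mean_error, 1e-10)
  expect_error(compare_point_clouds(A[1:2, ], A[1:2, ]), "fewer than 3")
})
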