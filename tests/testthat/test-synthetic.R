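# Synthetic rig sampling, scenario point distributions, observation noise
# and the board-constrained gold standard.

test_that("sampled rigs sit exactly on their circles and aim at the origin", {
  cfg <- rig_config()
  rig <- sample_rig(cfg, seed = 11)
  expect_length(rig, 10)
  for (cm in rig) {
    cc <- pose_center(cm$pose)
    r <- if (cm$category == "far") 2.8 else 1.2
    h <- if (cm$category == "far") 2.8 else 1.4
    expect_equal(sqrt(cc[1]^2 + cc[2]^2), r, tolerance = 1e-12)
    expect_equal(cc[3], h, tolerance = 1e-12)
    axis <- as.numeric(t(cm$pose$R) %*% c(0, 0, 1))
    expect_equal(sum(axis * (-cc) / sqrt(sum(cc^2))), 1, tolerance = 1e-12)
  }
  # seeded RNG contract
  rig2 <- sample_rig(cfg, seed = 11)
  expect_identical(rig, rig2)
  rig3 <- sample_rig(cfg, seed = 12)
  expect_false(isTRUE(all.equal(pose_center(rig[[1]]$pose),
                                pose_center(rig3[[1]]$pose))))
})

test_that("scenario point distributions satisfy their geometric constraints", {
  gf <- generate_points(scenario_config("grid_floor"), seed = 3)
  expect_equal(nrow(gf$points), 3200)
  expect_true(all(gf$points[, 3] == 0))
  xs <- sort(unique(gf$points[, 1]))
  expect_equal(diff(xs), rep(diff(xs)[1], length(xs) - 1), tolerance = 1e-9)

  bf <- generate_points(scenario_config("board_floor", n_boards = 10), seed = 3)
  expect_true(all(bf$points[, 3] == 0))
  expect_true(all(sqrt(bf$points[, 1]^2 + bf$points[, 2]^2) <= 3 + 1e-9))
  expect_equal(nrow(bf$points), 10 * 96)

  rig <- sample_rig(rig_config(), seed = 4)
  bv <- generate_points(scenario_config("board_volume", n_boards = 12),
                        seed = 3, rig = rig)
  rad <- sqrt(bv$points[, 1]^2 + bv$points[, 2]^2)
  expect_true(all(rad <= 3 + 1e-9))
  expect_true(all(bv$points[, 3] >= -1e-9 & bv$points[, 3] <= 1.5 + 1e-9))
  # every board faces at least two cameras
  centers <- t(vapply(rig, function(cm) pose_center(cm$pose), numeric(3)))
  for (b in seq_along(bv$boards)) {
    nrm <- as.numeric(bv$boards[[b]]$R %*% c(0, 0, 1))
    ctr <- bv$boards[[b]]$t
    facing <- sum((centers - matrix(ctr, nrow(centers), 3, byrow = TRUE)) %*% nrm > 0)
    expect_gte(facing, 2)
  }
})

test_that("zero-noise observations reproduce exact reprojections and targets are met", {
  rig <- sample_rig(rig_config(), seed = 5)
  scene <- generate_points(scenario_config("grid_floor"), seed = 6)
  tr <- generate_observations(rig, scene, sigma_px = 0, seed = 7)
  obs <- tr$observations
  Ks <- msmcalib:::rig_intrinsics(rig)
  poses <- msmcalib:::rig_poses(rig)
  for (cid in unique(obs$camera_id)[1:3]) {
    sel <- obs$camera_id == cid
    X <- scene$points[match(obs$marker_id[sel], scene$marker_id), ]
    px <- project_point(Ks[[cid]], poses[[cid]], X)
    expect_equal(cbind(obs$x[sel], obs$y[sel]), px, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  cnt <- table(obs$camera_id)
  cats <- vapply(rig, `[[`, character(1), "category")
  names(cats) <- vapply(rig, `[[`, character(1), "camera_id")
  expect_true(all(cnt[names(cats)[cats == "far"]] == 3000))
  expect_true(all(cnt[names(cats)[cats == "near"]] == 2000))
})

test_that("observation noise has the requested standard deviation within 2%", {
  rig <- sample_rig(rig_config(), seed = 5)
  scene <- generate_points(scenario_config("grid_floor"), seed = 6)
  key <- function(d) paste(d$camera_id, d$marker_id)
  d <- unlist(lapply(7:9, function(s) {
    clean <- generate_observations(rig, scene, sigma_px = 0, seed = s,
                                   targets = NULL)
    noisy <- generate_observations(rig, scene, sigma_px = 0.75, seed = s,
                                   targets = NULL)
    a <- clean$observations; b <- noisy$observations
    m <- match(key(a), key(b))
    c(b$x[m] - a$x, b$y[m] - a$y)
  }))
  expect_gt(length(d), 1e5)
  expect_lt(abs(stats::sd(d) - 0.75) / 0.75, 0.02)
  expect_lt(abs(mean(d)), 0.01)
})

test_that("a board facing away from a camera contributes no observations to it", {
  cfg <- rig_config(n_far = 2, n_near = 1)
  rig <- sample_rig(cfg, seed = 9)
  scenario <- scenario_config("board_volume", n_boards = 1)
  # construct a single board whose front (+z local) faces straight down
  L <- msmcalib:::board_local_points(scenario)
  scene <- list(points = L %*% t(rot_from_rotvec(c(pi, 0, 0))) +
                  matrix(c(0, 0, 1), nrow(L), 3, byrow = TRUE),
                marker_id = seq_len(nrow(L)) - 1L,
                board_meta = data.frame(marker_id = seq_len(nrow(L)) - 1L,
                                        board_idx = 1, lx = L[, 1],
                                        ly = L[, 2], lz = 0),
                boards = list(list(R = rot_from_rotvec(c(pi, 0, 0)),
                                   t = c(0, 0, 1))))
  tr <- generate_observations(rig, scene, sigma_px = 0, seed = 2, targets = NULL)
  expect_equal(nrow(tr$observations), 0)
})

test_that("the board-constrained gold standard is exact on noiseless data", {
  cfg <- rig_config(n_far = 4, n_near = 2)
  rig <- sample_rig(cfg, seed = 13)
  scene <- generate_points(scenario_config("board_floor", n_boards = 8),
                           seed = 14, rig = rig)
  tr <- generate_observations(rig, scene, sigma_px = 0, seed = 15,
                              targets = NULL)
  fit <- calibrate_with_board_constraint(tr, scene, msmcalib:::rig_intrinsics(rig),
                                         options = list(seed = 1))
  expect_lt(fit$ba$objective, 1e-10)
  pe <- pose_error(fit$poses, msmcalib:::rig_poses(rig))
  expect_lt(pe$rotation_rmse_deg, 1e-5)
  expect_lt(pe$translation_rmse_m, 1e-6)
  # gauge-fixed parameter count bookkeeping
  expect_equal(fit$ba$n_parameters,
               6 * (length(fit$registered) - 1) + 6 * length(fit$boards))
})

test_that("the experiment driver aggregates reproducibly and degrades with noise", {
  cfg <- rig_config(n_far = 3, n_near = 2)
  sa <- list(n_boards = 12, grid_n = 400, targets = c(near = 300, far = 400))
  out <- run_experiment(cfg, scenarios = c("grid_floor", "board_floor"),
                        sigmas = c(0, 1), n_repeats = 2, seed = 42,
                        scenario_args = sa)
  expect_equal(out$n_failed, 0)
  agg <- out$aggregates
  z <- agg[agg$sigma == 0, ]
  expect_true(all(z$rot_rmse_deg < 1e-5))
  expect_true(all(z$trans_rmse_m < 1e-5))
  n <- agg[agg$sigma == 1, ]
  for (sck in unique(agg$scenario))
    expect_gt(n$rot_rmse_deg[n$scenario == sck], z$rot_rmse_deg[z$scenario == sck])
  out2 <- run_experiment(cfg, scenarios = c("grid_floor", "board_floor"),
                         sigmas = c(0, 1), n_repeats = 2, seed = 42,
                         scenario_args = sa)
  expect_identical(out$results, out2$results)
})
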