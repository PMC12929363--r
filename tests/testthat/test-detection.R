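# Marker rendering, detection, diagonal-intersection centers, scale fusion
# and track building.

test_that("diagonal-intersection center is exact on squares and projectively equivariant", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(center_from_corners(sq), c(0.5, 0.5), tolerance = 1e-14)
  set.seed(71)
  base <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  c0 <- center_from_corners(base)
  for (i in 1:500) {
    H <- diag(3) + matrix(rnorm(9, 0, 0.15), 3, 3)
    if (abs(det(H)) < 0.1) next
    warped <- apply_homography(H, base)
    if (!msmcalib:::quad_convex(warped)) next
    expect_equal(center_from_corners(warped), apply_homography(H, c0),
                 tolerance = 1e-9)
  }
  expect_error(center_from_corners(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))),
               "degenerate")
})

test_that("rendered projector frames are fully detected with sub-pixel centers", {
  sch <- make_schedule(n_arrays = 4, markers_per_array = 8, grid_nx = 4,
                       grid_ny = 2, offset_grid = 2, scales = c(1, 2, 4))
  fr <- render_projector_frame(sch, array_idx = 1, scale_idx = 2)
  det <- detect_frame(fr$image)
  expect_equal(nrow(det), 8)
  expect_setequal(det$symbol_id, fr$markers$marker_id)
  for (i in seq_len(nrow(det))) {
    truth <- fr$markers[fr$markers$marker_id == det$symbol_id[i], ]
    ctr <- center_from_corners(matrix(as.numeric(det[i, paste0(c("x", "y"),
                                                               rep(1:4, each = 2))]),
                                      4, 2, byrow = TRUE))
    expect_lt(sqrt(sum((ctr - c(truth$cx, truth$cy))^2)), 0.3)
  }
})

test_that("blank frames yield no detections", {
  expect_equal(nrow(detect_frame(matrix(0, 200, 300))), 0)
  expect_equal(nrow(detect_frame(matrix(0.05, 200, 300))), 0)
})

test_that("consecutive array frames shift all detected centers by the schedule offset", {
  sch <- make_schedule(n_arrays = 4, markers_per_array = 8, grid_nx = 4,
                       grid_ny = 2, offset_grid = 2, scales = c(1, 2, 4))
  d0 <- detect_frame(render_projector_frame(sch, 0, 3)$image)
  d1 <- detect_frame(render_projector_frame(sch, 1, 3)$image)
  c0 <- t(vapply(seq_len(nrow(d0)), function(i)
    center_from_corners(matrix(as.numeric(d0[i, 3:10]), 4, 2, byrow = TRUE)),
    numeric(2)))
  c1 <- t(vapply(seq_len(nrow(d1)), function(i)
    center_from_corners(matrix(as.numeric(d1[i, 3:10]), 4, 2, byrow = TRUE)),
    numeric(2)))
  m0 <- sch$markers[match(d0$symbol_id, sch$markers$marker_id), ]
  m1 <- sch$markers[match(d1$symbol_id, sch$markers$marker_id), ]
  off_true <- c(m1$cx[1] - m0$cx[1], m1$cy[1] - m0$cy[1])
  shift <- colMeans(c1) - colMeans(c0)
  expect_equal(shift, off_true, tolerance = 0.05)
})

test_that("a far viewpoint resolves only the large marker scales", {
  sch <- make_schedule(n_arrays = 1, markers_per_array = 8, grid_nx = 4,
                       grid_ny = 2, offset_grid = 1, scales = c(1, 2.8, 8))
  g <- projector_floor_homography(480, c(1920, 1080))
  K <- hd_intrinsics()
  P_far <- look_at_pose(c(3.4, 0.3, 2.8), c(0, 0, 0))
  n_det <- vapply(1:3, function(si)
    nrow(detect_frame(render_camera_view(sch, 0, si, g, K, P_far)$image)),
    numeric(1))
  expect_lt(n_det[1], 8)         # smallest scale mostly unresolvable
  expect_equal(n_det[3], 8)      # largest scale fully detected
  expect_true(all(diff(n_det) >= 0))
})

test_that("scale fusion aggregates robustly and rejects outliers as specified", {
  consensus <- fuse_scales(rbind(c(50, 60), c(50, 60), c(50, 60)), scales = 1:3)
  expect_equal(consensus$center, c(50, 60))
  expect_equal(consensus$spread_px, 0)
  # stated median/MAD case: third center is a gross outlier
  f <- fuse_scales(rbind(c(100, 100), c(100.2, 100.1), c(140, 90)),
                   scales = 1:3, gate_px = 2)
  expect_equal(f$center, c(100.1, 100.05), tolerance = 1e-12)
  expect_equal(f$n_used, 2)
  expect_equal(f$scales_seen, c(1, 2))
  single <- fuse_scales(matrix(c(12.5, 7.5), 1, 2), scales = 4)
  expect_equal(single$center, c(12.5, 7.5))
  expect_equal(single$scales_seen, 4)
  # permutation invariance
  cs <- rbind(c(10, 10), c(10.4, 9.9), c(10.2, 10.1), c(30, 30))
  f1 <- fuse_scales(cs, scales = 1:4)
  f2 <- fuse_scales(cs[c(3, 1, 4, 2), ], scales = c(3, 1, 4, 2))
  expect_equal(f1$center, f2$center)
  expect_equal(f1$scales_seen, f2$scales_seen)
  # irreconcilable spread fails the gate
  expect_null(fuse_scales(rbind(c(0, 0), c(5, 5), c(10, 0), c(0, 10)),
                          scales = 1:4, gate_px = 2))
})

test_that("track building groups observations per marker and flags short tracks", {
  obs <- data.frame(
    camera_id = c(rep("a", 10), rep("b", 10), rep("c", 10)),
    marker_id = rep(1:10, 3), x = runif(30, 0, 100), y = runif(30, 0, 100))
  tr <- build_tracks(obs)
  expect_equal(nrow(tr$tracks), 10)
  expect_true(all(tr$tracks$length == 3))
  expect_true(all(tr$tracks$usable))
  obs2 <- data.frame(camera_id = c("a", "a", "b", "b"),
                     marker_id = c(1, 2, 2, 3), x = 1:4, y = 1:4)
  tr2 <- build_tracks(obs2)
  expect_equal(tr2$tracks$length[tr2$tracks$marker_id == 2], 2)
  expect_false(tr2$tracks$usable[tr2$tracks$marker_id == 1])
  expect_false(tr2$tracks$usable[tr2$tracks$marker_id == 3])
  dup <- rbind(obs2, obs2[1, ])
  expect_error(build_tracks(dup), "integrity")
})

test_that("pairwise correspondence counts match the construction", {
  obs <- data.frame(
    camera_id = c(rep("a", 5), rep("b", 4), rep("c", 2)),
    marker_id = c(1:5, 2:5, 4:5), x = 0, y = 0)
  pc <- msmcalib:::pair_correspondence_counts(build_tracks(obs))
  expect_equal(pc$n_shared[pc$camera_a == "a" & pc$camera_b == "b"], 4L)
  expect_equal(pc$n_shared[pc$camera_a == "a" & pc$camera_b == "c"], 2L)
  expect_equal(pc$n_shared[pc$camera_a == "b" & pc$camera_b == "c"], 2L)
})
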