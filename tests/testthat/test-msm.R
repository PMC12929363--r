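# Multi-scale markers, projection schedules and floor coordinates.

test_that("an MSM's scaled instances all fix the marker center exactly", {
  set.seed(61)
  for (i in 1:100) {
    p <- runif(2, 100, 1800)
    scales <- sort(unique(runif(sample(1:7, 1), 0.5, 9)))
    msm <- make_msm(pattern_spec(1), p, scales)
    for (si in seq_along(scales)) {
      corners <- msm_instance_corners(msm, si)
      ctr <- center_from_corners(corners)
      expect_equal(ctr, p, tolerance = 1e-12)
    }
  }
  single <- make_msm(pattern_spec(5, base_side = 0.1), c(10, 20), 1)
  expect_equal(single$scales, 1)
  expect_error(make_msm(pattern_spec(1), c(0, 0), c(1, -2)), "positive")
  expect_error(make_msm(pattern_spec(1), c(0, 0), c(2, 1)), "increasing")
})

test_that("the seven-scale set spans marker sides from 5 cm to 40 cm", {
  scales <- c(1.0, 1.4, 2.0, 3.0, 4.0, 6.0, 8.0)
  msm <- make_msm(pattern_spec(0, base_side = 0.05), c(960, 540), scales)
  px_per_m <- 480
  sides_m <- vapply(seq_along(scales), function(si) {
    q <- msm_instance_corners(msm, si, px_per_m)
    mean(sqrt(rowSums((q - q[c(2, 3, 4, 1), ])^2))) / px_per_m
  }, numeric(1))
  expect_equal(min(sides_m), 0.05, tolerance = 1e-12)
  expect_equal(max(sides_m), 0.40, tolerance = 1e-12)
  expect_equal(sides_m, 0.05 * scales, tolerance = 1e-12)
})

test_that("the default schedule produces 3200 distinct in-bounds centers", {
  sch <- make_schedule()
  expect_equal(nrow(sch$markers), 3200)
  expect_equal(nrow(unique(sch$markers[, c("cx", "cy")])), 3200)
  expect_equal(sch$n_arrays * sch$markers_per_array, 3200)
  # marker_id <-> (array, within) encoding is injective
  expect_equal(anyDuplicated(sch$markers$marker_id), 0)
  expect_equal(sch$markers$marker_id,
               sch$markers$array_idx * sch$markers_per_array + sch$markers$within_idx)
  expect_true(all(sch$markers$cx >= 0 & sch$markers$cx <= 1919))
  expect_true(all(sch$markers$cy >= 0 & sch$markers$cy <= 1079))
  expect_false(any(sch$markers$clipped_at_max_scale))
})

test_that("a single-array schedule reproduces the base grid", {
  sch <- make_schedule(n_arrays = 1, markers_per_array = 8, grid_nx = 4,
                       grid_ny = 2, offset_grid = 1)
  expect_equal(nrow(sch$markers), 8)
  W <- 1920; H <- 1080; m <- 120
  cw <- (W - 2 * m) / 4; ch <- (H - 2 * m) / 2
  expect_equal(sort(unique(sch$markers$cx)), m + (0:3 + 0.5) * cw)
  expect_equal(sort(unique(sch$markers$cy)), m + (0:1 + 0.5) * ch)
})

test_that("floor coordinates agree with a direct homography map and lie on z = 0", {
  sch <- make_schedule(n_arrays = 4, markers_per_array = 8, grid_nx = 4,
                       grid_ny = 2, offset_grid = 2)
  g <- matrix(c(0.002, 1e-4, 0, -2e-4, -0.0021, 0, -1.9, 1.1, 1), 3, 3)
  fc <- floor_coordinates(sch, g)
  for (i in seq_len(nrow(fc))) {
    direct <- apply_homography(g, as.numeric(sch$markers[i, c("cx", "cy")]))
    expect_equal(c(fc$X[i], fc$Y[i]), direct, tolerance = 1e-10)
  }
  expect_true(all(fc$Z == 0))
  expect_error(floor_coordinates(sch, matrix(0, 3, 3)), "invalid homography")
})

test_that("schedule descriptors round-trip through the YAML format", {
  sch <- make_schedule(n_arrays = 9, markers_per_array = 8, grid_nx = 4,
                       grid_ny = 2, offset_grid = 3, scales = c(1, 2.8, 8))
  path <- tempfile(fileext = ".yaml")
  save_schedule(sch, path)
  sch2 <- load_schedule(path)
  expect_equal(sch2$markers, sch$markers)
  expect_equal(sch2$scales, sch$scales)
  unlink(path)
})
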