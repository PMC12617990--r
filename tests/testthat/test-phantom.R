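test_that("phantom generation is deterministic given config + seed", {
  arts <- list(artifact_spec("dropout_slices", volumes = 3L, slices = 5:6, factor = 0.2))
  a <- make_phantom(small_phantom_config(seed = 77, artifacts = arts, noise_sigma = 0.05))
  b <- make_phantom(small_phantom_config(seed = 77, artifacts = arts, noise_sigma = 0.05))
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$masks$data, b$masks$data)
  expect_identical(a$truth$expected_red, b$truth$expected_red)
  c <- make_phantom(small_phantom_config(seed = 78, artifacts = arts, noise_sigma = 0.05))
  expect_false(identical(a$series$data, c$series$data))
})

test_that("noiseless in-brain mean intensity is non-increasing in b", {
  ph <- make_phantom(small_phantom_config(seed = 5))
  bt <- ph$series$btable
  means <- vapply(seq_len(length(bt)), function(t) {
    mean(ph$series$data[, , , t][ph$masks$data[, , , t] == 1])
  }, 0)
  ord <- order(bt$bvals)
  expect_true(all(diff(means[ord]) <= 1e-12))
})

test_that("clean noiseless phantom passes QC and truth agrees", {
  ph <- make_phantom(small_phantom_config(seed = 2))
  report <- run_qc(ph$series, ph$masks)
  expect_length(red_volumes(report), 0L)
  expect_length(ph$truth$expected_red, 0L)
  sc <- score_detection(report, ph$truth)
  expect_equal(sc$specificity, 1)
  expect_equal(sc$agreement, 1)
})

test_that("expected red set equals run_qc output on noiseless phantoms (oracle equivalence)", {
  arts <- list(
    artifact_spec("dropout_slices", volumes = c(4L, 12L), slices = 6:8, factor = 0.1),
    artifact_spec("volume_drift", volumes = 2L, rel_change = -0.1),   # b=10: flagged
    artifact_spec("volume_drift", volumes = 20L, rel_change = -0.1),  # b=1000: tolerated
    artifact_spec("com_shift", volumes = 8L, shift_mm = c(3, 0, 0))
  )
  ph <- make_phantom(small_phantom_config(seed = 13, artifacts = arts))
  report <- run_qc(ph$series, ph$masks)
  expect_identical(red_volumes(report), ph$truth$expected_red)
  # the drift at b=10 (threshold ~2.6%) is red, the same drift at b=1000
  # (threshold ~27.9%) is tolerated, and a pure COM shift is not red
  expect_true(2L %in% ph$truth$expected_red)
  expect_false(20L %in% ph$truth$expected_red)
  expect_false(8L %in% ph$truth$expected_red)
})

test_that("com_shift moves the COM by exactly the scripted whole-voxel shift", {
  arts <- list(artifact_spec("com_shift", volumes = 6L, shift_mm = c(3, 0, 0)))
  ph <- make_phantom(small_phantom_config(seed = 19, artifacts = arts))
  feats <- compute_all_features(ph$series, ph$masks)
  trace <- inter_volume_l2(feats)
  expect_equal(trace$l2_mm[5], 3, tolerance = 1e-9)
  expect_equal(trace$l2_mm[6], 3, tolerance = 1e-9)
  expect_equal(trace$l2_mm[-(5:6)], rep(0, length(trace$l2_mm) - 2),
               tolerance = 1e-9)
  # truth log records the true COM
  expect_equal(ph$truth$per_volume$true_com_x[6] - ph$truth$per_volume$true_com_x[5],
               3, tolerance = 1e-9)
  # non-whole-voxel shifts are rejected at generation time
  bad <- small_phantom_config(seed = 19, artifacts = list(
    artifact_spec("com_shift", volumes = 6L, shift_mm = c(3, 4, 0))))
  expect_error(make_phantom(bad), "whole number of voxels")
})

test_that("volume_drift hits its target and interacts with b as designed", {
  arts <- list(artifact_spec("volume_drift", volumes = 1L, rel_change = 0.1))
  # drift on a b=0 volume: 10% > 2% -> red (volume 1 is the drifted one,
  # so every *other* volume differs from the reference by ~10%)
  ph <- make_phantom(small_phantom_config(seed = 23, artifacts = arts))
  tv <- ph$truth$per_volume$true_volume_mm3
  expect_equal(tv[1] / tv[2], 1.1, tolerance = 5e-3)
  report <- run_qc(ph$series, ph$masks)
  # reference = drifted vol 1; all b<=80 volumes now exceed their threshold
  expect_true(all(which(ph$series$btable$bvals <= 80)[-1] %in% red_volumes(report)))
  expect_identical(red_volumes(report), ph$truth$expected_red)
})

test_that("crop_shift produces boundary contact and a red cropping flag", {
  arts <- list(artifact_spec("crop_shift", volumes = 10L, shift_mm = c(15, 0, 0)))
  ph <- make_phantom(small_phantom_config(seed = 29, artifacts = arts))
  f <- compute_volume_features(ph$series, ph$masks, 10L)
  expect_gt(f$boundary_fraction, 0)
  report <- run_qc(ph$series, ph$masks)
  expect_true(report$verdicts[[10]]$flag_cropped)
  expect_true(10L %in% ph$truth$expected_red)
  # an equally large com_shift without crop permission errors out
  bad <- small_phantom_config(seed = 29, artifacts = list(
    artifact_spec("com_shift", volumes = 10L, shift_mm = c(15, 0, 0))))
  expect_error(make_phantom(bad), "outside the grid")
})

test_that("score_detection produces standard 2x2 metrics", {
  arts <- list(artifact_spec("dropout_slices", volumes = c(3L, 7L),
                             slices = 5:7, factor = 0.1))
  ph <- make_phantom(small_phantom_config(seed = 37, artifacts = arts))
  report <- run_qc(ph$series, ph$masks)
  sc <- score_detection(report, ph$truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)
  # a report that flags everything: sensitivity 1, specificity 0
  all_red <- report
  for (i in seq_along(all_red$verdicts)) all_red$verdicts[[i]]$status <- "red"
  sc2 <- score_detection(all_red, ph$truth)
  expect_equal(sc2$sensitivity, 1)
  expect_equal(sc2$specificity, 0)
})

test_that("phantom rejects invalid configurations", {
  expect_error(phantom_config(seed = 1, grid = c(26, 26, 14),
                              semi_axes_mm = c(200, 10, 10)) |> make_phantom(),
               "does not fit")
  expect_error(phantom_config(grid = c(26, 26, 14)), "seed is required")
  expect_error(artifact_spec("dropout_slices", volumes = 1L, slices = 2L,
                             factor = 1.2), "factor")
  expect_error(artifact_spec("volume_drift", volumes = 1L, rel_change = 1.5),
               "rel_change")
  expect_error(make_phantom(small_phantom_config(seed = 1, artifacts = list(
    artifact_spec("dropout_slices", volumes = 50L, slices = 2L, factor = 0.1)))),
               "beyond the series")
})
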