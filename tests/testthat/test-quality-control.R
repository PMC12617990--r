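test_that("dynamic threshold matches its closed form and limits", {
  cfg <- qc_config()
  expect_equal(dynamic_threshold(0, cfg), 0.02)
  # closed-form evaluations at protocol b-values
  expect_equal(dynamic_threshold(200, cfg), 0.3 * (1 - exp(-0.4)) + 0.02)
  expect_equal(dynamic_threshold(200, cfg), 0.11890399, tolerance = 1e-7)
  expect_equal(dynamic_threshold(1000, cfg), 0.3 * (1 - exp(-2)) + 0.02)
  expect_equal(dynamic_threshold(1000, cfg), 0.2793994, tolerance = 1e-7)
  # asymptote alpha + f and monotonicity
  expect_equal(dynamic_threshold(1e9, cfg), 0.32)
  b <- seq(0, 5000, by = 1)
  expect_true(all(diff(dynamic_threshold(b, cfg)) > 0))
  expect_true(all(dynamic_threshold(b, cfg) <= cfg$alpha + cfg$f_offset))
  expect_error(dynamic_threshold(-1, cfg), ">= 0")
  # alpha = 0 collapses to the offset
  cfg0 <- qc_config(alpha = 0)
  expect_equal(dynamic_threshold(c(0, 100, 5000), cfg0), rep(0.02, 3))
})

test_that("dropout rule: uniform volumes clean, 40% deficit flagged, 35% is the strict boundary", {
  s <- toy_series(grid = c(8L, 8L, 6L), t = 1L, intensity = 100)
  m <- box_masks(s, i = 2:7, j = 2:7, k = 1:6)
  expect_length(detect_dropout_slices(s, m, 1L), 0L)

  # attenuate slice 3 to 60% of the volume mean computed *with* the deficit
  n_slices_in_mask <- 6
  att <- function(factor) {
    s2 <- s
    s2$data[, , 3, 1] <- 100 * factor
    s2
  }
  # deficit relative to the new volume mean: slice = 100f, vmean = 100(5+f)/6
  rel_deficit <- function(factor) 1 - factor * 6 / (5 + factor)
  expect_gt(rel_deficit(0.6), 0.35)
  expect_equal(detect_dropout_slices(att(0.6), m, 1L), 3L)

  # boundary: solve rel_deficit(factor) = 0.35 -> factor = 0.65*5/(6-0.65)
  f_star <- 0.65 * 5 / (6 - 0.65)
  expect_equal(rel_deficit(f_star), 0.35)
  # just past the boundary: flagged; just short of it: clean
  expect_equal(detect_dropout_slices(att(f_star * 0.999), m, 1L), 3L)
  expect_length(detect_dropout_slices(att(f_star * 1.001), m, 1L), 0L)
})

test_that("slices under the voxel-count floor are exempt from the dropout rule", {
  s <- toy_series(grid = c(8L, 8L, 6L), t = 1L, intensity = 100)
  m <- array(0, dim = dim(s$data))
  m[2:7, 2:7, 2:5, 1] <- 1
  m[4, 4, 6, 1] <- 1                       # single-voxel polar cap
  s$data[, , 6, 1] <- 1                    # would be a dropout if eligible
  ms <- mask_series(m, s)
  expect_length(detect_dropout_slices(s, ms, 1L), 0L)
  cfg <- qc_config(min_mask_voxels_per_slice = 1L)
  expect_equal(detect_dropout_slices(s, ms, 1L, cfg), 6L)
})

test_that("volume-change flag follows the b-value-dependent threshold", {
  s <- toy_series(grid = c(20L, 20L, 10L), t = 1L, bvals = 0)
  mref <- box_masks(s, i = 2:19, j = 2:19, k = 2:9)
  ref <- compute_volume_features(s, mref, 1L)

  make_feat <- function(rel, b) {
    f <- ref
    f$brain_volume <- ref$brain_volume * (1 + rel)
    f$b_value <- b
    f
  }
  # identical volume never flags
  expect_false(classify_volume(make_feat(0, 0), ref)$flag_volume)
  expect_false(classify_volume(make_feat(0, 1000), ref)$flag_volume)
  # 3% change at b=0 exceeds f=2%
  v <- classify_volume(make_feat(0.03, 0), ref)
  expect_true(v$flag_volume)
  expect_identical(v$status, "red")
  # 25% change at b=1000 is under the 27.94% threshold (two-sided)
  expect_false(classify_volume(make_feat(0.25, 1000), ref)$flag_volume)
  expect_false(classify_volume(make_feat(-0.25, 1000), ref)$flag_volume)
  expect_true(classify_volume(make_feat(-0.30, 1000), ref)$flag_volume)
  # green volumes carry zero priority
  expect_equal(classify_volume(make_feat(0, 0), ref)$priority_score, 0)
  expect_error(classify_volume(make_feat(0, 0),
                               local({r <- ref; r$n_mask_voxels <- 0L; r})),
               "invalid reference")
})

test_that("verdicts are invariant to global intensity scaling and in-plane axis swap", {
  case <- random_small_case(101)
  rep1 <- run_qc(case$series, case$masks)
  scaled <- case$series
  scaled$data <- scaled$data * 7.3
  rep2 <- run_qc(scaled, case$masks)
  expect_identical(vapply(rep1$verdicts, `[[`, "", "status"),
                   vapply(rep2$verdicts, `[[`, "", "status"))
  expect_identical(red_volumes(rep1), red_volumes(rep2))

  # permute the two in-plane axes (slice axis is 3)
  perm <- case$series
  perm$data <- aperm(case$series$data, c(2, 1, 3, 4))
  perm$voxel_size <- case$series$voxel_size[c(2, 1, 3)]
  pm <- case$masks
  pm$data <- aperm(case$masks$data, c(2, 1, 3, 4))
  rep3 <- run_qc(diffusion_series(perm$data, perm$voxel_size,
                                  diag(c(perm$voxel_size, 1)),
                                  case$series$btable),
                 pm)
  expect_identical(red_volumes(rep1), red_volumes(rep3))
})

test_that("run_qc matches the brute-force oracle on random small series", {
  for (seed in 1:30) {
    case <- random_small_case(1000 + seed)
    rep_fast <- run_qc(case$series, case$masks)
    oracle <- qc_bruteforce(case$series, case$masks)
    expect_identical(red_volumes(rep_fast), oracle$red,
                     info = paste("seed", seed))
    for (t in seq_along(rep_fast$verdicts)) {
      v <- rep_fast$verdicts[[t]]
      expect_identical(v$flag_dropout, oracle$flags$flag_dropout[t],
                       info = paste("dropout, seed", seed, "vol", t))
      expect_identical(v$flag_volume, oracle$flags$flag_volume[t],
                       info = paste("volume, seed", seed, "vol", t))
      expect_identical(v$flag_cropped, oracle$flags$flag_cropped[t],
                       info = paste("cropped, seed", seed, "vol", t))
      expect_identical(v$dropout_slices, as.integer(oracle$dropout[[t]]),
                       info = paste("slices, seed", seed, "vol", t))
    }
  }
})

test_that("reference policy first_clean_b0 skips a dropout-corrupted first dynamic", {
  s <- toy_series(t = 5L, bvals = c(0, 0, 10, 10, 1000))
  m <- box_masks(s)
  s$data[, , 3, 1] <- 1                # first dynamic has a dropout slice
  cfg <- qc_config(reference_volume_policy = "first_clean_b0")
  report <- run_qc(s, m, cfg)
  expect_equal(report$reference_index, 2L)
  expect_equal(run_qc(s, m)$reference_index, 1L)
  # reference's own volume change is zero
  expect_equal(report$verdicts[[2]]$volume_change_rel, 0)
})

test_that("empty-mask volumes are red and run_qc needs at least one usable volume", {
  s <- toy_series(t = 3L)
  m <- array(0, dim = dim(s$data))
  m[3:6, 3:6, 2:5, c(1, 3)] <- 1
  report <- run_qc(s, mask_series(m, s))
  expect_identical(report$verdicts[[2]]$status, "red")
  expect_true(report$verdicts[[2]]$flag_empty_mask)
  expect_true(is.na(report$verdicts[[2]]$volume_change_rel))
  expect_error(run_qc(s, mask_series(array(0, dim = dim(s$data)), s)),
               "no usable volumes")
})

test_that("alpha sweep counts disagreements against ground truth", {
  drift <- 0.16    # above threshold(1000) for small alpha, below for large
  arts <- list(artifact_spec("volume_drift", volumes = 20L, rel_change = drift),
               artifact_spec("dropout_slices", volumes = 4L, slices = 6:7, factor = 0.2))
  ph <- make_phantom(small_phantom_config(seed = 31, artifacts = arts))
  sweep <- alpha_sweep(ph$series, ph$masks, ph$truth,
                       alphas = seq(0.1, 0.5, by = 0.05))
  expect_equal(names(sweep), c("alpha", "n_flagged", "disagreement"))
  # more permissive alpha never flags more volumes
  expect_true(all(diff(sweep$n_flagged) <= 0))
  # at the truth's own alpha (0.3) the disagreement is zero on noiseless data
  expect_equal(sweep$disagreement[which.min(abs(sweep$alpha - 0.3))], 0L)
})
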