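#' b-value-dependent volume-change threshold
#'
#' The tolerated relative change in segmented brain volume grows with the
#' diffusion weighting, because the CSF rim surrounding the fetal brain
#' attenuates with b and the segmentation shrinks accordingly:
#'
#' \deqn{T(b) = \alpha (1 - e^{-b \cdot ADC_{ref}}) + f}
#'
#' At b = 0 the threshold equals the fixed segmentation-error allowance
#' `f_offset`; it increases monotonically and saturates at
#' `alpha + f_offset`.
#'
#' @param b_value Diffusion weighting, s/mm^2 (scalar or vector, >= 0).
#' @param config A [qc_config].
#' @return Threshold fraction(s), same length as `b_value`.
#' @export
dynamic_threshold <- function(b_value, config = qc_config()) {
  if (any(!is.finite(b_value)) || any(b_value < 0)) stop("b_value must be finite and >= 0")
  config$alpha * (1 - exp(-b_value * config$adc_ref)) + config$f_offset
}

#' Detect dropout (black) slices in one volume
#'
#' A slice is a dropout when its mean in-mask intensity falls strictly
#' below `(1 - slice_deficit)` times the mean in-mask intensity of the
#' whole brain volume. Slices with fewer than
#' `min_mask_voxels_per_slice` in-mask voxels are exempt: the polar caps
#' of the brain hold a handful of voxels whose means are unstable and
#' naturally darker.
#'
#' @param series A [diffusion_series].
#' @param masks The companion [mask_series].
#' @param index Volume number (1-based).
#' @param config A [qc_config].
#' @return Integer vector of dropout slice indices (possibly empty).
#' @export
detect_dropout_slices <- function(series, masks, index, config = qc_config()) {
  f <- compute_volume_features(series, masks, index)
  dropout_slices_from_features(f, config)
}

dropout_slices_from_features <- function(features, config) {
  if (features$n_mask_voxels == 0L) return(integer(0))
  eligible <- features$slice_mask_counts >= config$min_mask_voxels_per_slice &
    features$slice_mask_counts > 0L
  cutoff <- (1 - config$slice_deficit) * features$volume_mean_intensity
  which(eligible & !is.na(features$slice_mean_intensities) &
          features$slice_mean_intensities < cutoff)
}

#' Classify one volume against the reference
#'
#' Applies the three per-volume rules: dropout slices, relative
#' volume change against the reference volume compared to the
#' b-value-dependent threshold (two-sided, strict), and FOV cropping
#' (boundary-contact fraction above tolerance). A volume with an empty
#' mask is red with all features missing.
#'
#' The priority score used for re-acquisition ordering is
#' `n_dropout + max(0, excess)/threshold + cropped`, i.e. dropout-slice
#' count dominates, relative volume excess and cropping add fractional /
#' unit weight; it is 0 for green volumes. Empty-mask volumes receive a
#' score of `n_slices + 2` so they outrank any plausible dropout count.
#'
#' @param features `volume_features` of the volume under test.
#' @param reference `volume_features` of the reference volume (the first
#'   dynamic under the default policy).
#' @param config A [qc_config].
#' @param dropout_slices Optional precomputed dropout slice indices;
#'   computed from `features` when `NULL`.
#' @return An object of class `volume_verdict`.
#' @export
classify_volume <- function(features, reference, config = qc_config(),
                            dropout_slices = NULL) {
  if (reference$n_mask_voxels == 0L) stop("invalid reference: empty segmentation")
  thr <- dynamic_threshold(features$b_value, config)

  if (features$n_mask_voxels == 0L) {
    return(structure(list(
      index = features$index, b_value = features$b_value,
      dropout_slices = integer(0), volume_change_rel = NA_real_,
      threshold_b = thr, flag_dropout = FALSE, flag_volume = FALSE,
      flag_cropped = FALSE, flag_empty_mask = TRUE, status = "red",
      priority_score = length(features$slice_mask_counts) + 2
    ), class = "volume_verdict"))
  }

  if (is.null(dropout_slices)) {
    dropout_slices <- dropout_slices_from_features(features, config)
  }
  vcr <- abs(features$brain_volume - reference$brain_volume) / reference$brain_volume
  flag_dropout <- length(dropout_slices) > 0L
  flag_volume <- vcr > thr
  flag_cropped <- features$boundary_fraction > config$boundary_fraction_tol
  red <- flag_dropout || flag_volume || flag_cropped
  score <- if (red) {
    length(dropout_slices) + max(0, vcr - thr) / thr + as.numeric(flag_cropped)
  } else 0

  structure(list(
    index = features$index, b_value = features$b_value,
    dropout_slices = as.integer(dropout_slices), volume_change_rel = vcr,
    threshold_b = thr, flag_dropout = flag_dropout, flag_volume = flag_volume,
    flag_cropped = flag_cropped, flag_empty_mask = FALSE,
    status = if (red) "red" else "green", priority_score = score
  ), class = "volume_verdict")
}

#' @export
print.volume_verdict <- function(x, ...) {
  cat(sprintf("<volume_verdict> vol %d (b=%g): %s [dropout %d | dV %.3f vs %.3f | cropped %s]\n",
              x$index, x$b_value, x$status, length(x$dropout_slices),
              ifelse(is.na(x$volume_change_rel), NaN, x$volume_change_rel),
              x$threshold_b, x$flag_cropped))
  invisible(x)
}

choose_reference <- function(features, dropouts, config) {
  usable <- which(vapply(features, function(f) f$n_mask_voxels > 0L, TRUE))
  if (length(usable) == 0L) stop("no usable volumes: all masks empty")
  first <- usable[1]
  if (config$reference_volume_policy == "first_clean_b0" &&
      length(dropouts[[first]]) > 0L) {
    for (i in usable) {
      if (features[[i]]$b_value == 0 && length(dropouts[[i]]) == 0L) return(i)
    }
  }
  first
}

#' Run the full per-volume quality assessment
#'
#' Computes features for every volume, chooses the reference volume per
#' `reference_volume_policy`, classifies each volume green/red, and
#' assembles the inter-volume COM motion trace. Deterministic for fixed
#' inputs and configuration.
#'
#' @param series A [diffusion_series].
#' @param masks The companion [mask_series].
#' @param config A [qc_config].
#' @return An object of class `qc_report` with fields `verdicts` (one per
#'   volume), `trace` ([inter_volume_l2] output or `NULL` if undefined),
#'   `reference_index` and `config`.
#' @export
run_qc <- function(series, masks, config = qc_config()) {
  features <- compute_all_features(series, masks)
  dropouts <- lapply(features, dropout_slices_from_features, config = config)
  ref <- choose_reference(features, dropouts, config)
  verdicts <- lapply(seq_along(features), function(i) {
    classify_volume(features[[i]], features[[ref]], config,
                    dropout_slices = dropouts[[i]])
  })
  trace <- tryCatch(inter_volume_l2(features), error = function(e) NULL)
  structure(list(verdicts = verdicts, trace = trace, reference_index = ref,
                 config = config),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  st <- vapply(x$verdicts, `[[`, "", "status")
  cat(sprintf("<qc_report> %d volumes: %d green, %d red (reference volume %d)\n",
              length(st), sum(st == "green"), sum(st == "red"), x$reference_index))
  if (!is.null(x$trace)) {
    cat(sprintf("  mean inter-volume L2: %.2f mm (%.2f cm)\n",
                x$trace$mean_l2_mm, x$trace$mean_l2_mm / 10))
  }
  invisible(x)
}

#' Red (corrupted) volume indices of a report
#'
#' @param report A `qc_report`.
#' @return Integer vector of red volume indices.
#' @export
red_volumes <- function(report) {
  which(vapply(report$verdicts, `[[`, "", "status") == "red")
}

#' Sensitivity sweep over the threshold scale alpha
#'
#' Re-runs the quality assessment for each candidate `alpha` and counts
#' per-volume disagreements (symmetric difference) between the flagged
#' set and the ground-truth corrupted set, mirroring how the scale is
#' calibrated against expert annotation.
#'
#' @param series A [diffusion_series].
#' @param masks The companion [mask_series].
#' @param truth A `phantom_truth` (see [make_phantom]) or an integer
#'   vector of truly-corrupted volume indices.
#' @param alphas Candidate scale values (default `seq(0.1, 0.5, 0.05)`).
#' @param config Base configuration; only `alpha` varies.
#' @return A data.frame with columns `alpha`, `n_flagged`, `disagreement`.
#' @export
alpha_sweep <- function(series, masks, truth, alphas = seq(0.1, 0.5, by = 0.05),
                        config = qc_config()) {
  true_red <- if (inherits(truth, "phantom_truth")) truth$expected_red else as.integer(truth)
  t_len <- n_volumes(series)
  if (any(true_red < 1L | true_red > t_len)) stop("truth indices out of range")
  res <- lapply(alphas, function(a) {
    cfg <- config
    cfg$alpha <- a
    rep_a <- run_qc(series, masks, cfg)
    flagged <- red_volumes(rep_a)
    data.frame(alpha = a, n_flagged = length(flagged),
               disagreement = length(setdiff(flagged, true_red)) +
                 length(setdiff(true_red, flagged)))
  })
  do.call(rbind, res)
}
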