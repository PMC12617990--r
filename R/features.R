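#' Per-volume geometric and intensity features
#'
#' Computes, for one volume of a diffusion series, the features that the
#' quality rules consume: segmented brain volume (mm^3), world-space
#' centre of mass of the binary mask, fraction of mask voxels touching the
#' FOV boundary, and per-slice / whole-volume in-mask intensity
#' statistics along the through-plane axis.
#'
#' The centre of mass is the unweighted centroid of mask voxel centres
#' mapped through the affine (0-based voxel indices); it is therefore
#' invariant to the diffusion contrast changing with b. Boundary contact
#' is evaluated on all six FOV faces.
#'
#' For an empty mask the intensity and geometry fields are `NA` and
#' `n_mask_voxels` is 0; downstream classification forces such volumes red.
#'
#' @param series A [diffusion_series].
#' @param masks The companion [mask_series].
#' @param index Volume number (1-based).
#' @return An object of class `volume_features`.
#' @export
compute_volume_features <- function(series, masks, index) {
  t_len <- n_volumes(series)
  if (index < 1L || index > t_len) stop("volume index out of range")
  vol <- series$data[, , , index]
  msk <- masks$data[, , , index]
  d <- dim(msk)
  sa <- series$slice_axis
  n_slices <- d[sa]
  vox_vol <- prod(series$voxel_size)
  b_value <- series$btable$bvals[index]

  idx <- which(msk == 1, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) {
    return(structure(list(
      index = index, b_value = b_value, n_mask_voxels = 0L,
      brain_volume = NA_real_, com_world = rep(NA_real_, 3),
      boundary_fraction = NA_real_,
      slice_mask_counts = integer(n_slices),
      slice_mean_intensities = rep(NA_real_, n_slices),
      volume_mean_intensity = NA_real_
    ), class = "volume_features"))
  }

  # world COM: affine applied to 0-based voxel centres
  vox0 <- cbind(idx - 1L, 1)
  com_world <- as.numeric(series$affine %*% (colSums(vox0) / n))[1:3]

  on_face <- (idx[, 1] == 1L | idx[, 1] == d[1] |
              idx[, 2] == 1L | idx[, 2] == d[2] |
              idx[, 3] == 1L | idx[, 3] == d[3])
  intens <- vol[msk == 1]
  slice_of <- idx[, sa]
  counts <- tabulate(slice_of, nbins = n_slices)
  sums <- numeric(n_slices)
  agg <- tapply(intens, slice_of, sum)
  sums[as.integer(names(agg))] <- as.numeric(agg)
  slice_means <- ifelse(counts > 0, sums / counts, NA_real_)

  structure(list(
    index = index, b_value = b_value, n_mask_voxels = n,
    brain_volume = n * vox_vol,
    com_world = com_world,
    boundary_fraction = sum(on_face) / n,
    slice_mask_counts = counts,
    slice_mean_intensities = slice_means,
    volume_mean_intensity = mean(intens)
  ), class = "volume_features")
}

#' @export
print.volume_features <- function(x, ...) {
  cat(sprintf("<volume_features> vol %d (b=%g): %d voxels, %.1f mm^3, COM (%s) mm, boundary %.3f\n",
              x$index, x$b_value, x$n_mask_voxels, x$brain_volume,
              paste(format(x$com_world, digits = 4), collapse = ", "),
              x$boundary_fraction))
  invisible(x)
}

#' Features for every volume of a series
#'
#' @inheritParams compute_volume_features
#' @return A list of `volume_features`, one per volume.
#' @export
compute_all_features <- function(series, masks) {
  lapply(seq_len(n_volumes(series)), function(i) {
    compute_volume_features(series, masks, i)
  })
}

#' Inter-volume centre-of-mass motion trace
#'
#' The Euclidean (L2) distance in mm between the brain centres of mass of
#' consecutive volumes, a measure of inter-volume motion. Pairs involving
#' an empty-mask volume are recorded as `NA`. The scalar summary
#' `mean_l2_mm` is the arithmetic mean over defined pairs.
#'
#' @param features List of `volume_features` as returned by
#'   [compute_all_features].
#' @return An object of class `motion_trace` with fields `l2_mm`
#'   (length t - 1) and `mean_l2_mm`.
#' @export
inter_volume_l2 <- function(features) {
  usable <- vapply(features, function(f) f$n_mask_voxels > 0L, TRUE)
  if (sum(usable) < 2L) stop("trace undefined: fewer than 2 usable volumes")
  t_len <- length(features)
  l2 <- rep(NA_real_, t_len - 1L)
  for (i in seq_len(t_len - 1L)) {
    if (usable[i] && usable[i + 1L]) {
      l2[i] <- sqrt(sum((features[[i + 1L]]$com_world - features[[i]]$com_world)^2))
    }
  }
  structure(list(l2_mm = l2, mean_l2_mm = mean(l2, na.rm = TRUE)),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d pairs, mean L2 %.2f mm (%.2f cm), max %.2f mm\n",
              length(x$l2_mm), x$mean_l2_mm, x$mean_l2_mm / 10,
              suppressWarnings(max(x$l2_mm, na.rm = TRUE))))
  invisible(x)
}
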