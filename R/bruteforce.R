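# Naive reference implementation of the per-volume quality rules.
#
# Deliberately written as direct per-volume / per-slice loops over the
# arrays, sharing no helper code with run_qc() (which works from pooled
# per-volume feature tables), so it can serve as an independent oracle
# for equivalence testing and for deriving the phantom's expected red
# set.

#' Brute-force quality assessment (reference oracle)
#'
#' A direct, loop-based reimplementation of the green/red classification,
#' independent of [run_qc]. Reference volume is always the first volume
#' with a non-empty mask (policy `"first"`).
#'
#' @param series A [diffusion_series].
#' @param masks The companion [mask_series].
#' @param config A [qc_config].
#' @return A list with `red` (integer indices), `flags` (data.frame of
#'   per-volume booleans) and `dropout` (list of slice indices).
#' @export
qc_bruteforce <- function(series, masks, config = qc_config()) {
  d <- dim(series$data)
  t_len <- d[4]
  sa <- series$slice_axis
  n_slices <- d[sa]
  vox_vol <- series$voxel_size[1] * series$voxel_size[2] * series$voxel_size[3]

  slice_grab <- function(arr3, s) {
    if (sa == 1L) arr3[s, , ] else if (sa == 2L) arr3[, s, ] else arr3[, , s]
  }

  vol_mm3 <- rep(NA_real_, t_len)
  cropped <- rep(NA, t_len)
  dropout <- vector("list", t_len)
  empty <- logical(t_len)

  for (t in seq_len(t_len)) {
    m <- masks$data[, , , t] == 1
    v <- series$data[, , , t]
    count <- sum(m)
    empty[t] <- count == 0L
    dropout[[t]] <- integer(0)
    if (count == 0L) next

    vol_mm3[t] <- count * vox_vol

    # boundary contact: mask voxels that are not strictly interior
    interior <- m
    interior[1, , ] <- FALSE; interior[d[1], , ] <- FALSE
    interior[, 1, ] <- FALSE; interior[, d[2], ] <- FALSE
    interior[, , 1] <- FALSE; interior[, , d[3]] <- FALSE
    touches <- count - sum(interior)
    cropped[t] <- touches / count > config$boundary_fraction_tol

    vmean <- sum(v[m]) / count
    bad <- integer(0)
    for (s in seq_len(n_slices)) {
      ms <- slice_grab(m, s)
      n_s <- sum(ms)
      if (n_s >= config$min_mask_voxels_per_slice && n_s > 0L) {
        slice_mean <- sum(slice_grab(v, s)[ms]) / n_s
        if (slice_mean < (1 - config$slice_deficit) * vmean) bad <- c(bad, s)
      }
    }
    dropout[[t]] <- bad
  }

  ref <- which(!empty)[1]
  if (is.na(ref)) stop("no usable volumes: all masks empty")

  flag_dropout <- logical(t_len)
  flag_volume <- logical(t_len)
  flag_cropped <- logical(t_len)
  red <- logical(t_len)
  for (t in seq_len(t_len)) {
    if (empty[t]) {
      red[t] <- TRUE
      next
    }
    b <- series$btable$bvals[t]
    thr <- config$alpha * (1 - exp(-b * config$adc_ref)) + config$f_offset
    flag_dropout[t] <- length(dropout[[t]]) > 0L
    flag_volume[t] <- abs(vol_mm3[t] - vol_mm3[ref]) / vol_mm3[ref] > thr
    flag_cropped[t] <- isTRUE(cropped[t])
    red[t] <- flag_dropout[t] || flag_volume[t] || flag_cropped[t]
  }

  list(red = which(red),
       flags = data.frame(index = seq_len(t_len), flag_dropout = flag_dropout,
                          flag_volume = flag_volume, flag_cropped = flag_cropped,
                          flag_empty_mask = empty, red = red),
       dropout = dropout)
}
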