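#' Artifact specification for the synthetic phantom
#'
#' @param kind One of `"dropout_slices"` (multiply listed slices of the
#'   signal by an attenuation factor), `"com_shift"` (translate brain and
#'   mask by a whole-voxel shift in mm), `"volume_drift"` (grow/shrink the
#'   mask only, emulating segmentation error at high b), `"crop_shift"`
#'   (translate so the brain is clipped by the FOV boundary).
#' @param volumes Target volume index(es), 1-based.
#' @param slices Slice indices for `dropout_slices`.
#' @param factor Attenuation factor in `[0, 1)` for `dropout_slices`.
#' @param shift_mm Length-3 shift (mm) for `com_shift` / `crop_shift`;
#'   must be a whole number of voxels per axis.
#' @param rel_change Signed relative mask-volume change in `(-1, 1)` for
#'   `volume_drift`.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind = c("dropout_slices", "com_shift",
                                   "volume_drift", "crop_shift"),
                          volumes, slices = NULL, factor = NULL,
                          shift_mm = NULL, rel_change = NULL) {
  kind <- match.arg(kind)
  volumes <- as.integer(volumes)
  if (length(volumes) < 1L || any(volumes < 1L)) stop("volumes must be positive indices")
  if (kind == "dropout_slices") {
    if (is.null(slices) || is.null(factor)) stop("dropout_slices needs slices and factor")
    if (factor < 0 || factor >= 1) stop("attenuation factor must lie in [0, 1)")
  } else if (kind %in% c("com_shift", "crop_shift")) {
    if (is.null(shift_mm) || length(shift_mm) != 3L) stop(kind, " needs a length-3 shift_mm")
  } else {
    if (is.null(rel_change) || abs(rel_change) >= 1) stop("volume_drift needs |rel_change| < 1")
  }
  structure(list(kind = kind, volumes = volumes, slices = as.integer(slices),
                 factor = factor, shift_mm = shift_mm, rel_change = rel_change),
            class = "artifact_spec")
}

#' Phantom configuration
#'
#' Describes a synthetic fetal-brain diffusion acquisition: an ellipsoidal
#' parenchyma surrounded by a CSF rim of diffusivity 0.002 mm^2/s, imaged
#' with a multi-b-value protocol, with optional injected artifacts and
#' Rician noise.
#'
#' Voxel signal follows the two-compartment IVIM decay
#' `S(b) = S0 * (f * exp(-b D*) + (1 - f) * exp(-b D))` with per-class
#' parameters. The mask is the exact outer-ellipsoid support (parenchyma
#' plus rim), perturbed only by `volume_drift` artifacts.
#'
#' @param grid Grid sizes (default `c(64, 64, 35)`, echoing a 35-slice
#'   axial protocol at desk scale).
#' @param voxel_size Voxel edge lengths in mm (default 3 isotropic).
#' @param bt Acquisition [btable] (default [default_btable]: b = 0 plus
#'   seven shells at 10--1000 s/mm^2, three orthogonal directions each).
#' @param semi_axes_mm Parenchyma ellipsoid semi-axes, mm.
#' @param csf_rim_mm CSF rim thickness, mm.
#' @param center_mm Ellipsoid centre in world mm (default: grid centre).
#' @param parenchyma,csf Tissue parameter lists with elements `S0`, `f`,
#'   `D`, `Dstar` (mm^2/s where applicable).
#' @param noise_sigma Rician noise level relative to parenchyma `S0`
#'   (0 disables noise; e.g. 0.05 is SNR 20).
#' @param artifacts List of [artifact_spec]s.
#' @param seed Integer RNG seed (required).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(64L, 64L, 35L), voxel_size = c(3, 3, 3),
                           bt = default_btable(),
                           semi_axes_mm = c(33, 42, 27), csf_rim_mm = 6,
                           center_mm = NULL,
                           parenchyma = list(S0 = 100, f = 0.1, D = 0.0012, Dstar = 0.05),
                           csf = list(S0 = 150, f = 0, D = 0.002, Dstar = 0.002),
                           noise_sigma = 0, artifacts = list(), seed) {
  if (missing(seed)) stop("seed is required")
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 4L)) stop("grid must be 3 sizes >= 4")
  voxel_size <- as.numeric(voxel_size)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (any(semi_axes_mm <= 0) || csf_rim_mm < 0) stop("invalid ellipsoid geometry")
  if (is.null(center_mm)) center_mm <- (grid - 1) * voxel_size / 2
  if (inherits(artifacts, "artifact_spec")) artifacts <- list(artifacts)
  stopifnot(all(vapply(artifacts, inherits, TRUE, "artifact_spec")))
  t_len <- length(bt)
  for (a in artifacts) {
    if (any(a$volumes > t_len)) stop("artifact targets a volume beyond the series")
    if (a$kind == "dropout_slices" && any(a$slices < 1L | a$slices > grid[3])) {
      stop("artifact slices out of range")
    }
  }
  structure(list(grid = grid, voxel_size = voxel_size, bt = bt,
                 semi_axes_mm = semi_axes_mm, csf_rim_mm = csf_rim_mm,
                 center_mm = center_mm, parenchyma = parenchyma, csf = csf,
                 noise_sigma = noise_sigma, artifacts = artifacts,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

ivim_signal <- function(b, p) {
  p$S0 * (p$f * exp(-b * p$Dstar) + (1 - p$f) * exp(-b * p$D))
}

# squared normalized ellipsoid radius at every voxel centre
ellipsoid_r2 <- function(grid, voxel_size, center_mm, semi_axes) {
  x <- ((seq_len(grid[1]) - 1) * voxel_size[1] - center_mm[1]) / semi_axes[1]
  y <- ((seq_len(grid[2]) - 1) * voxel_size[2] - center_mm[2]) / semi_axes[2]
  z <- ((seq_len(grid[3]) - 1) * voxel_size[3] - center_mm[3]) / semi_axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

#' Generate a synthetic diffusion series, masks and ground truth
#'
#' Builds the noiseless two-compartment signal per volume, applies the
#' configured artifacts, adds Rician noise, and derives the ground-truth
#' log: per-volume injected artifacts, true mask centre of mass and
#' volume, and the expected red set. The expected red set is computed by
#' running the independent brute-force rule oracle ([qc_bruteforce]) on
#' the noiseless data, so it states which volumes the rules *should* flag
#' at the given rule configuration.
#'
#' @param config A [phantom_config].
#' @param qc A [qc_config] used to derive the expected red set.
#' @return A list: `series` ([diffusion_series]), `masks`
#'   ([mask_series]), `truth` (`phantom_truth`).
#' @export
make_phantom <- function(config, qc = qc_config()) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  g <- config$grid
  vs <- config$voxel_size
  bt <- config$bt
  t_len <- length(bt)
  semi_out <- config$semi_axes_mm + config$csf_rim_mm
  fov_max <- (g - 1) * vs

  base_fits <- all(config$center_mm - semi_out >= 0) &&
    all(config$center_mm + semi_out <= fov_max)
  has_crop <- any(vapply(config$artifacts, function(a) a$kind == "crop_shift", TRUE))
  if (!base_fits && !has_crop) stop("ellipsoid does not fit the grid (no crop_shift requested)")

  # collect per-volume artifact assignments
  shift_of <- matrix(0, nrow = 3, ncol = t_len)
  crop_vol <- logical(t_len)
  drift_of <- rep(NA_real_, t_len)
  drop_slices <- vector("list", t_len)
  drop_factor <- rep(NA_real_, t_len)
  kinds_of <- vector("list", t_len)
  for (a in config$artifacts) {
    for (v in a$volumes) {
      kinds_of[[v]] <- c(kinds_of[[v]], a$kind)
      if (a$kind %in% c("com_shift", "crop_shift")) {
        sv <- a$shift_mm / vs
        if (any(abs(sv - round(sv)) > 1e-6)) {
          stop("shift_mm must be a whole number of voxels per axis")
        }
        shift_of[, v] <- a$shift_mm
        if (a$kind == "crop_shift") crop_vol[v] <- TRUE
      } else if (a$kind == "volume_drift") {
        drift_of[v] <- a$rel_change
      } else {
        drop_slices[[v]] <- sort(unique(c(drop_slices[[v]], a$slices)))
        drop_factor[v] <- a$factor
      }
    }
  }

  data <- array(0, dim = c(g, t_len))
  mdata <- array(0, dim = c(g, t_len))
  clean <- array(0, dim = c(g, t_len))      # noiseless, for truth derivation
  com_true <- matrix(NA_real_, nrow = 3, ncol = t_len)
  vol_true <- numeric(t_len)
  vox_vol <- prod(vs)

  r2_cache <- list()
  for (t in seq_len(t_len)) {
    key <- paste(shift_of[, t], collapse = ",")
    if (is.null(r2_cache[[key]])) {
      ctr <- config$center_mm + shift_of[, t]
      if (!crop_vol[t] && base_fits &&
          !all(ctr - semi_out >= 0 & ctr + semi_out <= fov_max)) {
        stop("com_shift pushes the brain outside the grid; use crop_shift")
      }
      r2_cache[[key]] <- list(
        inner = ellipsoid_r2(g, vs, ctr, config$semi_axes_mm),
        outer = ellipsoid_r2(g, vs, ctr, semi_out)
      )
    }
    r2 <- r2_cache[[key]]
    par_m <- r2$inner <= 1
    out_m <- r2$outer <= 1
    csf_m <- out_m & !par_m

    b <- bt$bvals[t]
    sig <- array(0, dim = g)
    sig[par_m] <- ivim_signal(b, config$parenchyma)
    sig[csf_m] <- ivim_signal(b, config$csf)

    if (length(drop_slices[[t]])) {
      sig[, , drop_slices[[t]]] <- sig[, , drop_slices[[t]]] * drop_factor[t]
    }

    msk <- out_m
    if (!is.na(drift_of[t])) {
      n0 <- sum(out_m)
      target <- max(1L, round(n0 * (1 + drift_of[t])))
      ord <- order(r2$outer)           # grow/shrink along the ellipsoid surface
      msk <- array(FALSE, dim = g)
      msk[ord[seq_len(min(target, length(ord)))]] <- TRUE
    }

    clean[, , , t] <- sig
    mdata[, , , t] <- as.double(msk)

    idx <- which(msk, arr.ind = TRUE)
    vol_true[t] <- nrow(idx) * vox_vol
    if (nrow(idx)) com_true[, t] <- colMeans((idx - 1) %*% diag(vs))

    if (config$noise_sigma > 0) {
      sigma <- config$noise_sigma * config$parenchyma$S0
      nv <- prod(g)
      sig <- sqrt((sig + array(stats::rnorm(nv, 0, sigma), dim = g))^2 +
                    array(stats::rnorm(nv, 0, sigma), dim = g)^2)
    }
    data[, , , t] <- sig
  }

  affine <- diag(c(vs, 1))
  series <- diffusion_series(data, vs, affine, bt, slice_axis = 3L)
  masks <- mask_series(mdata, series)

  clean_series <- diffusion_series(clean, vs, affine, bt, slice_axis = 3L)
  oracle <- qc_bruteforce(clean_series, masks, qc)

  per_volume <- data.frame(
    index = seq_len(t_len),
    b_value = bt$bvals,
    artifacts = vapply(kinds_of, function(k) paste(unique(k), collapse = ","), ""),
    n_dropout_slices = vapply(drop_slices, length, 1L),
    dropout_factor = drop_factor,
    shift_x_mm = shift_of[1, ], shift_y_mm = shift_of[2, ], shift_z_mm = shift_of[3, ],
    rel_volume_change = drift_of,
    true_com_x = com_true[1, ], true_com_y = com_true[2, ], true_com_z = com_true[3, ],
    true_volume_mm3 = vol_true
  )
  truth <- structure(list(per_volume = per_volume,
                          dropout_slices = drop_slices,
                          expected_red = oracle$red,
                          qc_config = qc),
                     class = "phantom_truth")
  list(series = series, masks = masks, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d volumes, expected red: %s\n",
              nrow(x$per_volume),
              if (length(x$expected_red)) paste(x$expected_red, collapse = ", ") else "none"))
  invisible(x)
}

#' Score a QC report against phantom ground truth
#'
#' Standard volume-level 2x2 counts: a positive is a truly corrupted
#' volume (member of the expected red set), a detection is a red verdict.
#'
#' @param report A `qc_report`.
#' @param truth A `phantom_truth`.
#' @return A list: `sensitivity`, `specificity`, `agreement`, and the 2x2
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
score_detection <- function(report, truth) {
  t_len <- length(report$verdicts)
  if (t_len != nrow(truth$per_volume)) stop("report/truth length mismatch")
  flagged <- red_volumes(report)
  pos <- truth$expected_red
  neg <- setdiff(seq_len(t_len), pos)
  tp <- length(intersect(flagged, pos))
  fp <- length(intersect(flagged, neg))
  fn <- length(setdiff(pos, flagged))
  tn <- length(setdiff(neg, flagged))
  list(sensitivity = if (length(pos)) tp / length(pos) else NA_real_,
       specificity = if (length(neg)) tn / length(neg) else NA_real_,
       agreement = (tp + tn) / t_len,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
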