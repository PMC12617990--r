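#' Quality-control configuration
#'
#' Tunable parameters of the per-volume quality rules.
#'
#' @param alpha Scale of the b-value-dependent volume-change threshold
#'   (dimensionless, default 0.3).
#' @param f_offset Additive segmentation-error allowance of the same
#'   threshold (fraction, default 0.02: a fixed 2\% error for all volumes).
#' @param adc_ref Reference diffusivity governing how fast the threshold
#'   saturates with b (mm^2/s, default 0.002, the diffusivity of the CSF
#'   surrounding the fetal brain).
#' @param slice_deficit Relative intensity deficit at which a slice is
#'   declared a dropout (fraction, default 0.35: a slice whose in-mask mean
#'   is more than 35\% below the volume's in-mask mean is corrupted).
#' @param min_mask_voxels_per_slice Slices with fewer in-mask voxels are
#'   exempt from the dropout rule (count, default 5).
#' @param boundary_fraction_tol Cropping flag fires when the fraction of
#'   mask voxels touching the FOV boundary exceeds this (default 0).
#' @param max_iterations Re-acquisition iteration cap (default 2).
#' @param reference_volume_policy `"first"` (the first dynamic) or
#'   `"first_clean_b0"` (fall back to the first b = 0 volume without
#'   dropout slices when the first dynamic is itself dropout-flagged).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(alpha = 0.3, f_offset = 0.02, adc_ref = 0.002,
                      slice_deficit = 0.35, min_mask_voxels_per_slice = 5L,
                      boundary_fraction_tol = 0, max_iterations = 2L,
                      reference_volume_policy = c("first", "first_clean_b0")) {
  reference_volume_policy <- match.arg(reference_volume_policy)
  if (alpha < 0) stop("alpha must be >= 0")
  if (f_offset < 0 || f_offset >= 1) stop("f_offset must lie in [0, 1)")
  if (adc_ref <= 0) stop("adc_ref must be > 0")
  if (slice_deficit <= 0 || slice_deficit >= 1) stop("slice_deficit must lie in (0, 1)")
  if (min_mask_voxels_per_slice < 0) stop("min_mask_voxels_per_slice must be >= 0")
  if (boundary_fraction_tol < 0) stop("boundary_fraction_tol must be >= 0")
  if (max_iterations < 0) stop("max_iterations must be >= 0")
  structure(list(alpha = alpha, f_offset = f_offset, adc_ref = adc_ref,
                 slice_deficit = slice_deficit,
                 min_mask_voxels_per_slice = as.integer(min_mask_voxels_per_slice),
                 boundary_fraction_tol = boundary_fraction_tol,
                 max_iterations = as.integer(max_iterations),
                 reference_volume_policy = reference_volume_policy),
            class = "qc_config")
}

#' @export
print.qc_config <- function(x, ...) {
  cat("<qc_config>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a QC configuration from a YAML file
#'
#' Keys mirror the arguments of [qc_config]; missing keys take the
#' defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `qc_config`.
#' @export
read_qc_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(qc_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(qc_config, vals)
}

#' Write a QC configuration to a YAML file
#'
#' @param config A `qc_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
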