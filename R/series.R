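#' 4D diffusion-weighted series
#'
#' Couples a 4D intensity array (i, j, k, t) with its voxel geometry and
#' gradient table. World coordinates are obtained by applying the affine to
#' 0-based voxel indices, the NIfTI convention.
#'
#' @param data 4D non-negative numeric array.
#' @param voxel_size Length-3 voxel edge lengths, mm.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param bt A [btable] whose length equals `dim(data)[4]`.
#' @param slice_axis Through-plane array axis (1, 2 or 3); slices are
#'   indexed along this axis. Default 3 (axial stack).
#' @return An object of class `diffusion_series`.
#' @export
diffusion_series <- function(data, voxel_size, affine, bt, slice_axis = 3L) {
  if (length(dim(data)) != 4L) stop("expects 4D series")
  if (!inherits(bt, "btable")) stop("bt must be a btable")
  if (dim(data)[4] != length(bt)) stop("btable/series length mismatch")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) stop("voxel_size must be 3 positive values")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12) stop("affine must be an invertible 4x4 matrix")
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("slice_axis must be 1, 2 or 3")
  structure(list(data = data, voxel_size = voxel_size, affine = affine,
                 btable = bt, slice_axis = slice_axis),
            class = "diffusion_series")
}

#' @export
print.diffusion_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<diffusion_series> %d x %d x %d grid, %d volumes, voxels %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size), collapse = " x ")))
  print(x$btable)
  invisible(x)
}

n_volumes <- function(series) dim(series$data)[4]

#' Per-volume binary brain-mask series
#'
#' One binary mask per acquired volume, on the same grid as its companion
#' series. Values are stored as 0/1.
#'
#' @param data 4D array binarizable to 0/1 (values in `[0, 1]` are
#'   thresholded at 0.5).
#' @param series The companion [diffusion_series]; geometry must match.
#' @return An object of class `mask_series`.
#' @export
mask_series <- function(data, series) {
  if (length(dim(data)) != 4L) stop("expects 4D mask series")
  if (!all(dim(data) == dim(series$data))) stop("mask/series geometry mismatch")
  if (any(!is.finite(data)) || any(data < 0) || any(data > 1)) {
    stop("mask values must lie in [0, 1]")
  }
  m <- array(as.double(data >= 0.5), dim = dim(data))
  structure(list(data = m), class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_series> %d x %d x %d grid, %d volumes, %d total mask voxels\n",
              d[1], d[2], d[3], d[4], sum(x$data)))
  invisible(x)
}

#' Read a 4D diffusion series from disk
#'
#' @param dwi_path 4D NIfTI file.
#' @param bval_path,bvec_path FSL-style gradient table files.
#' @param slice_axis Through-plane axis; see [diffusion_series].
#' @return A validated `diffusion_series`.
#' @export
read_series <- function(dwi_path, bval_path, bvec_path, slice_axis = 3L) {
  img <- read_nifti(dwi_path)
  if (length(dim(img$data)) != 4L) stop("expects 4D series")
  bt <- read_btable(bval_path, bvec_path)
  if (length(bt) != dim(img$data)[4]) stop("btable/series length mismatch")
  diffusion_series(img$data, img$voxel_size, img$affine, bt, slice_axis)
}

#' Read a 4D mask series from disk
#'
#' @param mask_path 4D NIfTI file on the same grid as `series`.
#' @param series The companion [diffusion_series].
#' @return A `mask_series`.
#' @export
read_masks <- function(mask_path, series) {
  img <- read_nifti(mask_path)
  if (length(dim(img$data)) != 4L || !all(dim(img$data) == dim(series$data))) {
    stop("mask/series geometry mismatch")
  }
  mask_series(img$data, series)
}

#' Write a diffusion series (or mask series) to disk
#'
#' @param series A `diffusion_series`.
#' @param dwi_path Output NIfTI path.
#' @param bval_path,bvec_path Optional gradient-table output paths.
#' @param datatype NIfTI storage type; default `"float64"` keeps voxel
#'   data bitwise identical across a write/read round trip.
#' @return Invisibly, `dwi_path`.
#' @export
write_series <- function(series, dwi_path, bval_path = NULL, bvec_path = NULL,
                         datatype = "float64") {
  write_nifti(series$data, dwi_path, affine = series$affine,
              voxel_size = series$voxel_size, datatype = datatype)
  if (!is.null(bval_path) && !is.null(bvec_path)) {
    write_btable(series$btable, bval_path, bvec_path)
  }
  invisible(dwi_path)
}
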