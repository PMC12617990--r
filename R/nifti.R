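# Minimal NIfTI-1 (.nii / .nii.gz) reader and writer.
#
# Scope: single-file NIfTI-1 only, little- or big-endian, the numeric
# datatypes produced by scanners and common tools (uint8, int16, int32,
# float32, float64, uint16), scl_slope/scl_inter scaling, sform/qform
# affines. No extensions are interpreted; .hdr/.img pairs and NIfTI-2 are
# out of scope.

NIFTI_DTYPES <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE),
  uint16  = list(code = 512L, bitpix = 16L, what = "integer", size = 2L, signed = FALSE)
)

nifti_dtype_by_code <- function(code) {
  for (nm in names(NIFTI_DTYPES)) {
    if (NIFTI_DTYPES[[nm]]$code == code) {
      d <- NIFTI_DTYPES[[nm]]
      d$name <- nm
      return(d)
    }
  }
  stop("unsupported NIfTI datatype code: ", code)
}

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an
#' R array together with its voxel geometry. Intensity scaling
#' (`scl_slope`/`scl_inter`) is applied on read; the affine is taken from
#' the sform when `sform_code > 0`, else from the qform, else from
#' `pixdim` alone.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `affine` (4x4
#'   voxel-to-world matrix, mm, 0-based voxel indices), `voxel_size`
#'   (length-3, mm) and `datatype` (storage type name).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    close(con)
    con <- gzfile(path, "rb")
    sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }

  readBin(con, "raw", 35L)                                   # unused legacy fields
  dim_info <- readBin(con, "raw", 1L)
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                   # intent params/codes
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  bitpix <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 4L)                                    # slice_end (int16), slice_code, xyzt_units
  readBin(con, "double", 3L, size = 4L, endian = endian)     # cal_max, cal_min, slice_duration
  readBin(con, "double", 1L, size = 4L, endian = endian)     # toffset
  readBin(con, "integer", 2L, size = 4L, endian = endian)    # glmax, glmin
  readBin(con, "raw", 104L)                                  # descrip + aux_file
  qform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  quat <- readBin(con, "double", 6L, size = 4L, endian = endian)   # b,c,d, qoffset x,y,z
  srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16L)                                   # intent_name
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1")) stop("unsupported NIfTI magic (expected single-file 'n+1')")

  ndim <- dims[1]
  if (ndim < 1L || ndim > 7L) stop("invalid NIfTI dim[0]: ", ndim)
  shape <- dims[2:(1 + ndim)]
  nvox <- prod(shape)
  dt <- nifti_dtype_by_code(datatype)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))

  if (dt$name == "uint16") {
    # readBin has no unsigned 16-bit; read signed and fold negatives
    raw_vals <- readBin(con, "integer", nvox, size = 2L, signed = TRUE, endian = endian)
    vals <- ifelse(raw_vals < 0, raw_vals + 65536, raw_vals)
  } else {
    vals <- readBin(con, dt$what, nvox, size = dt$size, signed = dt$signed, endian = endian)
  }
  if (length(vals) != nvox) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(as.double(vals), dim = shape)

  pixdim_xyz <- abs(pixdim[2:4])
  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    qform_to_affine(quat[1:3], quat[4:6], pixdim_xyz, qfac = pixdim[1])
  } else {
    diag(c(pixdim_xyz, 1))
  }

  list(data = data, affine = affine, voxel_size = pixdim_xyz, datatype = dt$name)
}

qform_to_affine <- function(bcd, offset, pixdim_xyz, qfac = 1) {
  b <- bcd[1]; c <- bcd[2]; d <- bcd[3]
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 < 1e-7) 0 else sqrt(a2)
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d),           2 * (b * d + a * c),
    2 * (b * c + a * d),           a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c),           2 * (c * d + a * b),           a * a + d * d - b * b - c * c
  ), nrow = 3, byrow = TRUE)
  if (is.na(qfac) || qfac == 0) qfac <- 1
  S <- diag(c(pixdim_xyz[1], pixdim_xyz[2], pixdim_xyz[3] * qfac))
  rbind(cbind(R %*% S, offset), c(0, 0, 0, 1))
}

#' Write a NIfTI-1 image
#'
#' Writes an array as a single-file NIfTI-1 image; gzip compression is
#' chosen from the file extension. The affine is stored in the sform
#' (code 2); no intensity scaling is applied (`scl_slope = 1`).
#'
#' @param data Numeric array of 1 to 7 dimensions.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-world matrix (mm, 0-based voxel indices).
#' @param voxel_size Length-3 voxel edge lengths in mm; defaults to the
#'   column norms of `affine`.
#' @param datatype Storage type: one of `"uint8"`, `"int16"`, `"int32"`,
#'   `"float32"`, `"float64"`, `"uint16"`.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, affine = diag(4), voxel_size = NULL,
                        datatype = "float64") {
  if (!datatype %in% names(NIFTI_DTYPES)) stop("unsupported datatype: ", datatype)
  dt <- NIFTI_DTYPES[[datatype]]
  shape <- dim(data)
  if (is.null(shape)) shape <- length(data)
  ndim <- length(shape)
  if (ndim > 7L) stop("too many dimensions for NIfTI-1")
  if (is.null(voxel_size)) {
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }

  dims <- integer(8)
  dims[1] <- ndim
  dims[2:(1 + ndim)] <- shape
  if (ndim < 7L) dims[(2 + ndim):8] <- 1L
  pixdim <- numeric(8)
  pixdim[1] <- 1
  pixdim[2:4] <- c(voxel_size, 1, 1)[1:3]
  pixdim[5:8] <- 1

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wint <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wflt <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")

  wint(348L, 4L)                               # sizeof_hdr
  writeBin(raw(36L), con)                      # data_type, db_name, extents, session_error, regular, dim_info
  wint(dims, 2L)
  wflt(c(0, 0, 0))                             # intent_p1..p3
  wint(0L, 2L)                                 # intent_code
  wint(dt$code, 2L)
  wint(dt$bitpix, 2L)
  wint(0L, 2L)                                 # slice_start
  wflt(pixdim)
  wflt(352)                                    # vox_offset
  wflt(1); wflt(0)                             # scl_slope, scl_inter
  writeBin(raw(4L), con)                       # slice_end (int16), slice_code, xyzt_units
  wflt(c(0, 0, 0))                             # cal_max, cal_min, slice_duration
  wflt(0)                                      # toffset
  wint(c(0L, 0L), 4L)                          # glmax, glmin
  writeBin(raw(104L), con)                     # descrip, aux_file
  wint(0L, 2L)                                 # qform_code
  wint(2L, 2L)                                 # sform_code
  wflt(c(0, 0, 0))                             # quatern b,c,d
  wflt(affine[1:3, 4])                         # qoffset (informational)
  wflt(t(affine[1:3, ]))                       # srow_x, srow_y, srow_z
  writeBin(raw(16L), con)                      # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                       # extension flag

  vals <- as.vector(data)
  if (dt$what == "integer") {
    iv <- as.integer(round(vals))
    if (datatype == "uint16") iv <- ifelse(iv > 32767L, iv - 65536L, iv)
    writeBin(iv, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
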