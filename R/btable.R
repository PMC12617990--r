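#' Diffusion gradient table
#'
#' A b-table pairs each volume of a 4D diffusion series with its
#' diffusion-weighting strength (b-value, s/mm^2) and unit gradient
#' direction (b-vector). Volumes with b = 0 carry the zero vector.
#'
#' @param bvals Numeric vector of b-values, one per volume, all >= 0.
#' @param bvecs 3 x t numeric matrix of gradient directions. Directions for
#'   b > 0 must have unit norm within 1e-3 and are renormalized to exact
#'   unit length; directions for b = 0 are forced to the zero vector.
#' @return An object of class `btable`.
#' @export
btable <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L) stop("bvecs must be a 3 x t matrix")
  if (ncol(bvecs) != length(bvals)) stop("bval/bvec length mismatch")
  if (any(!is.finite(bvals)) || any(bvals < 0)) stop("b-values must be finite and >= 0")
  storage.mode(bvecs) <- "double"
  for (i in seq_along(bvals)) {
    nrm <- sqrt(sum(bvecs[, i]^2))
    if (bvals[i] == 0) {
      bvecs[, i] <- 0
    } else {
      if (abs(nrm - 1) > 1e-3) {
        stop(sprintf("b-vector %d has norm %.6f (must be unit within 1e-3)", i, nrm))
      }
      bvecs[, i] <- bvecs[, i] / nrm
    }
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "btable")
}

#' @export
length.btable <- function(x) length(x$bvals)

#' @export
print.btable <- function(x, ...) {
  ub <- sort(unique(x$bvals))
  cat(sprintf("<btable> %d volumes, b-values: %s s/mm^2\n",
              length(x$bvals), paste(ub, collapse = ", ")))
  invisible(x)
}

#' Subset a b-table by volume
#'
#' @param x A `btable`.
#' @param i Volume indices (1-based).
#' @param ... Unused.
#' @export
`[.btable` <- function(x, i, ...) {
  btable(x$bvals[i], x$bvecs[, i, drop = FALSE])
}

#' Read an FSL-style bval/bvec pair
#'
#' `bval` is a whitespace-separated row of b-values; `bvec` holds three
#' rows of direction components (x, y, z).
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A `btable`.
#' @export
read_btable <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path)) if (!file.exists(p)) stop("file not found: ", p)
  bvals <- scan(bval_path, what = double(), quiet = TRUE)
  bvec_lines <- readLines(bvec_path, warn = FALSE)
  bvec_lines <- bvec_lines[nzchar(trimws(bvec_lines))]
  if (length(bvec_lines) != 3L) stop("bvec file must have exactly 3 rows")
  rows <- lapply(bvec_lines, function(l) scan(text = l, what = double(), quiet = TRUE))
  nn <- vapply(rows, length, 1L)
  if (length(unique(nn)) != 1L) stop("ragged bvec file")
  bvecs <- do.call(rbind, rows)
  if (ncol(bvecs) != length(bvals)) stop("bval/bvec length mismatch")
  btable(bvals, bvecs)
}

#' Write an FSL-style bval/bvec pair
#'
#' Directions and b-values are written at full precision, preserving sign.
#'
#' @param bt A `btable`.
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_btable <- function(bt, bval_path, bvec_path) {
  stopifnot(inherits(bt, "btable"))
  writeLines(paste(format(bt$bvals, digits = 17, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  writeLines(apply(bt$bvecs, 1, function(r) {
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")
  }), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Default multi-b-value acquisition table
#'
#' One b = 0 volume followed by each non-zero b-value acquired along three
#' orthogonal directions (x, y, z), the standard compact IVIM-capable
#' fetal protocol (22 volumes for the default shell set).
#'
#' @param bvalues Non-zero shell b-values (s/mm^2).
#' @return A `btable` of length `1 + 3 * length(bvalues)`.
#' @export
default_btable <- function(bvalues = c(10, 50, 80, 200, 400, 600, 1000)) {
  bvals <- c(0, rep(bvalues, each = 3))
  bvecs <- cbind(c(0, 0, 0), do.call(cbind, rep(list(diag(3)), length(bvalues))))
  btable(bvals, bvecs)
}
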