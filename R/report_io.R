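# Serialization of QC reports (JSON) and re-acquisition plans
# (TSV manifest plus companion bval/bvec pair).

pkg_version <- function() as.character(utils::packageVersion("dmriqc"))

#' Write a QC report to JSON
#'
#' The document carries one verdict record per volume (features, flags,
#' status, priority score), the inter-volume L2 trace in mm, the
#' reference volume, a configuration echo and the software version.
#' Numeric values are written at full precision so the round trip is
#' lossless.
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  verdicts <- lapply(report$verdicts, function(v) {
    list(index = v$index, b_value = v$b_value,
         dropout_slices = as.integer(v$dropout_slices),
         volume_change_rel = v$volume_change_rel,
         threshold_b = v$threshold_b,
         flag_dropout = v$flag_dropout, flag_volume = v$flag_volume,
         flag_cropped = v$flag_cropped, flag_empty_mask = v$flag_empty_mask,
         status = v$status, priority_score = v$priority_score)
  })
  doc <- list(
    software = list(name = "dmriqc", version = pkg_version()),
    reference_index = report$reference_index,
    config = unclass(report$config),
    trace = if (is.null(report$trace)) NULL else
      list(l2_mm = report$trace$l2_mm, mean_l2_mm = report$trace$mean_l2_mm),
    verdicts = verdicts
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a QC report from JSON
#'
#' Inverse of [write_report]; restores classed objects.
#'
#' @param path JSON file written by [write_report].
#' @return A `qc_report`.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  verdicts <- lapply(doc$verdicts, function(v) {
    structure(list(
      index = as.integer(v$index), b_value = as.numeric(v$b_value),
      dropout_slices = as.integer(unlist(v$dropout_slices)),
      volume_change_rel = num1(v$volume_change_rel),
      threshold_b = as.numeric(v$threshold_b),
      flag_dropout = isTRUE(v$flag_dropout), flag_volume = isTRUE(v$flag_volume),
      flag_cropped = isTRUE(v$flag_cropped),
      flag_empty_mask = isTRUE(v$flag_empty_mask),
      status = v$status, priority_score = as.numeric(v$priority_score)
    ), class = "volume_verdict")
  })
  cfg_args <- doc$config
  config <- do.call(qc_config, cfg_args)
  trace <- if (is.null(doc$trace)) NULL else {
    structure(list(l2_mm = vapply(doc$trace$l2_mm, num1, 0),
                   mean_l2_mm = as.numeric(doc$trace$mean_l2_mm)),
              class = "motion_trace")
  }
  structure(list(verdicts = verdicts, trace = trace,
                 reference_index = as.integer(doc$reference_index),
                 config = config),
            class = "qc_report")
}

reacq_companion_paths <- function(path) {
  base <- sub("\\.[^.]*$", "", path)
  c(bval = paste0(base, ".bval"), bvec = paste0(base, ".bvec"))
}

#' Write a re-acquisition list for the scanner
#'
#' Writes (a) a tab-separated manifest with one row per planned volume
#' (`original_index`, `b_value`, `gx`, `gy`, `gz`, `priority_rank`) and
#' (b) a companion bval/bvec pair restricted to the planned volumes in
#' acquisition-priority order, next to the manifest (same basename,
#' `.bval`/`.bvec` extensions). An empty plan writes a header-only
#' manifest and empty bval/bvec files.
#'
#' @param plan A `reacq_plan` with directions (see
#'   [plan_with_directions]).
#' @param path Manifest output path (e.g. `plan.tsv`).
#' @return Invisibly, `path`.
#' @export
write_reacq_list <- function(plan, path) {
  items <- plan$items
  if (nrow(items) > 0L && anyNA(items$gx)) {
    stop("plan has no directions; call plan_with_directions() first")
  }
  cols <- c("original_index", "b_value", "gx", "gy", "gz", "priority_rank")
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- paste(cols, collapse = "\t")
  if (nrow(items) > 0L) {
    rows <- apply(items[, cols], 1, function(r) paste(fmt(r), collapse = "\t"))
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  cp <- reacq_companion_paths(path)
  if (nrow(items) > 0L) {
    bt <- btable(items$b_value, t(as.matrix(items[, c("gx", "gy", "gz")])))
    write_btable(bt, cp["bval"], cp["bvec"])
  } else {
    writeLines(character(0), cp["bval"])
    writeLines(character(0), cp["bvec"])
  }
  invisible(path)
}

#' Read a re-acquisition list
#'
#' Inverse of [write_reacq_list] (manifest only; the companion bval/bvec
#' pair is redundant).
#'
#' @param path Manifest path.
#' @param iteration Iteration number to attach (not stored in the
#'   manifest).
#' @return A `reacq_plan` (priority scores are not stored on disk and
#'   read back as `NA`).
#' @export
read_reacq_list <- function(path, iteration = 1L) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    items <- data.frame(original_index = integer(0), b_value = numeric(0),
                        gx = numeric(0), gy = numeric(0), gz = numeric(0),
                        priority_rank = integer(0), priority_score = numeric(0))
  } else {
    items <- data.frame(original_index = as.integer(df$original_index),
                        b_value = as.numeric(df$b_value),
                        gx = as.numeric(df$gx), gy = as.numeric(df$gy),
                        gz = as.numeric(df$gz),
                        priority_rank = as.integer(df$priority_rank),
                        priority_score = NA_real_)
  }
  structure(list(items = items, iteration = as.integer(iteration),
                 cap_reached = FALSE), class = "reacq_plan")
}
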