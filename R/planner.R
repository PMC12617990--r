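#' Build a prioritized re-acquisition plan
#'
#' Every red volume of the report enters the plan, ordered by decreasing
#' priority score (dropout-slice count dominating, volume excess and
#' cropping adding fractional / unit weight), ties broken by acquisition
#' order. Beyond the configured iteration cap the plan is empty and
#' carries a `cap_reached` marker.
#'
#' @param report A `qc_report` from [run_qc].
#' @param iteration 1-based re-acquisition iteration about to be run.
#' @param config A [qc_config].
#' @return An object of class `reacq_plan` with fields `items`
#'   (data.frame: `original_index`, `b_value`, `gx`, `gy`, `gz`,
#'   `priority_rank`, `priority_score`), `iteration`, `cap_reached`.
#' @export
build_plan <- function(report, iteration = 1L, config = report$config) {
  if (iteration < 1L) stop("iteration must be >= 1")
  empty_items <- data.frame(original_index = integer(0), b_value = numeric(0),
                            gx = numeric(0), gy = numeric(0), gz = numeric(0),
                            priority_rank = integer(0), priority_score = numeric(0))
  if (iteration > config$max_iterations) {
    return(structure(list(items = empty_items, iteration = as.integer(iteration),
                          cap_reached = TRUE), class = "reacq_plan"))
  }
  reds <- red_volumes(report)
  if (length(reds) == 0L) {
    return(structure(list(items = empty_items, iteration = as.integer(iteration),
                          cap_reached = FALSE), class = "reacq_plan"))
  }
  scores <- vapply(report$verdicts[reds], `[[`, 0, "priority_score")
  ord <- order(-scores, reds)
  reds <- reds[ord]
  scores <- scores[ord]
  bvals <- vapply(report$verdicts[reds], `[[`, 0, "b_value")
  items <- data.frame(
    original_index = reds,
    b_value = bvals,
    gx = NA_real_, gy = NA_real_, gz = NA_real_,
    priority_rank = seq_along(reds),
    priority_score = scores
  )
  structure(list(items = items, iteration = as.integer(iteration),
                 cap_reached = FALSE), class = "reacq_plan")
}

#' Attach gradient directions to a plan
#'
#' Plans built from a bare report carry b-values only; this fills the
#' direction columns from the series b-table.
#'
#' @param plan A `reacq_plan`.
#' @param bt The series [btable].
#' @return The plan with `gx`, `gy`, `gz` populated.
#' @export
plan_with_directions <- function(plan, bt) {
  if (nrow(plan$items) > 0L) {
    v <- bt$bvecs[, plan$items$original_index, drop = FALSE]
    plan$items$gx <- v[1, ]
    plan$items$gy <- v[2, ]
    plan$items$gz <- v[3, ]
  }
  plan
}

#' @export
print.reacq_plan <- function(x, ...) {
  cat(sprintf("<reacq_plan> iteration %d: %d volume(s)%s\n", x$iteration,
              nrow(x$items), if (x$cap_reached) " [iteration cap reached]" else ""))
  if (nrow(x$items)) print(x$items, row.names = FALSE)
  invisible(x)
}

#' Merge re-acquired volumes back into a series
#'
#' Replaces each planned volume with the corresponding volume of the
#' re-acquired series (matched by plan position); all other volumes and
#' the b-table are unchanged. The re-acquired series must carry one
#' volume per plan item, in plan order, with matching b-value and
#' direction (tolerance 1e-3).
#'
#' @param series The original [diffusion_series].
#' @param reacq A [diffusion_series] of the re-acquired volumes.
#' @param plan The `reacq_plan` the volumes answer.
#' @return A new `diffusion_series`.
#' @export
merge_series <- function(series, reacq, plan) {
  n_items <- nrow(plan$items)
  if (n_volumes(reacq) != n_items) stop("reacquisition/plan mismatch: cardinality")
  if (n_items == 0L) return(series)
  if (!all(dim(reacq$data)[1:3] == dim(series$data)[1:3])) {
    stop("reacquisition/plan mismatch: grid")
  }
  for (p in seq_len(n_items)) {
    idx <- plan$items$original_index[p]
    if (abs(reacq$btable$bvals[p] - series$btable$bvals[idx]) > 1e-3 ||
        any(abs(reacq$btable$bvecs[, p] - series$btable$bvecs[, idx]) > 1e-3)) {
      stop("reacquisition/plan mismatch: b-table")
    }
  }
  out <- series
  out$data[, , , plan$items$original_index] <- reacq$data
  out
}

#' Merge re-acquired masks back into a mask series
#'
#' @param masks Original [mask_series].
#' @param reacq_masks `mask_series` of the re-acquired volumes (plan order).
#' @param plan The `reacq_plan`.
#' @return A new `mask_series`.
#' @export
merge_masks <- function(masks, reacq_masks, plan) {
  n_items <- nrow(plan$items)
  if (dim(reacq_masks$data)[4] != n_items) stop("reacquisition/plan mismatch: cardinality")
  if (n_items == 0L) return(masks)
  out <- masks
  out$data[, , , plan$items$original_index] <- reacq_masks$data
  out
}

#' Iterative quality assessment with re-acquisition
#'
#' Runs the qc -> plan -> re-acquire -> merge loop until no volume is red
#' or the iteration cap is reached. The `reacq_provider` callback plays
#' the scanner: given a plan (with directions) it returns
#' `list(series = <diffusion_series of planned volumes>, masks =
#' <mask_series>)`.
#'
#' @param series A [diffusion_series].
#' @param masks The companion [mask_series].
#' @param reacq_provider Callback `function(plan)` returning re-acquired
#'   volumes and masks for the planned indices, in plan order.
#' @param config A [qc_config].
#' @return A list: `series`, `masks` (after all merges), `reports`
#'   (one `qc_report` per pass, the first being the initial assessment)
#'   and `plans` (the non-empty plans emitted, at most `max_iterations`).
#' @export
iterate_qc <- function(series, masks, reacq_provider, config = qc_config()) {
  reports <- list()
  plans <- list()
  report <- run_qc(series, masks, config)
  reports[[1]] <- report
  it <- 1L
  while (length(red_volumes(report)) > 0L && it <= config$max_iterations) {
    plan <- plan_with_directions(build_plan(report, it, config), series$btable)
    plans[[it]] <- plan
    provided <- reacq_provider(plan)
    if (!is.list(provided) || is.null(provided$series) || is.null(provided$masks)) {
      stop("reacq_provider must return list(series =, masks =)")
    }
    if (n_volumes(provided$series) != nrow(plan$items)) {
      stop("provider returned wrong number of volumes")
    }
    series <- merge_series(series, provided$series, plan)
    masks <- merge_masks(masks, provided$masks, plan)
    report <- run_qc(series, masks, config)
    reports[[length(reports) + 1L]] <- report
    it <- it + 1L
  }
  list(series = series, masks = masks, reports = reports, plans = plans)
}
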