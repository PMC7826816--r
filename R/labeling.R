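# Windowed imminent-precursor labeling and class rebalancing.
#
# A row is labelled 1 when it falls within W seconds *before* some
# precursor event (boundaries inclusive): 0 <= t(event) - t(row) <= W*1000.
# Rows during evocative (EO) and reinforcing (S^R) conditions are labelled
# by the time rule alone; rows after the last precursor keep label 0.

#' Assign imminent-precursor labels on the feature timeline
#'
#' @param fm a `feature_matrix` (or any tibble with `timestamp_ms`).
#' @param log an [event_log()] on the same session clock, or a plain
#'   numeric vector of precursor timestamps in ms.
#' @param window_s pre-event window W in seconds (default 90).
#' @param subject_id optional subject label stored on the result.
#' @return a `labeled_dataset`: `fm` plus a `label` column (integer 0/1),
#'   with `window_s` and `subject_id` attributes. A log without precursor
#'   events yields all-zero labels with a warning.
#' @export
assign_labels <- function(fm, log, window_s = 90, subject_id = NULL) {
  if (!is.numeric(window_s) || window_s <= 0) abort_parameter("window_s must be > 0")
  prec <- if (is.numeric(log)) {
    log
  } else {
    validate_event_log(log)
    log$timestamp_ms[log$event_kind == "precursor"]
  }
  if (!length(prec)) {
    warning("no precursor events; all labels are 0", call. = FALSE)
  }
  ts <- fm$timestamp_ms
  lab <- rep(0L, length(ts))
  w_ms <- window_s * 1000
  for (te in prec) lab[ts >= te - w_ms & ts <= te] <- 1L
  out <- dplyr::mutate(as_tibble(fm), label = lab)
  structure(out,
    class = c("labeled_dataset", class(tibble())),
    window_s = window_s, subject_id = subject_id
  )
}

#' Oversample the minority class to a 1:1 ratio
#'
#' Minority rows are duplicated by seeded sampling with replacement until
#' the two classes have equal counts; majority rows are untouched. Used
#' for the window-sensitivity analysis so accuracies at different W are
#' comparable despite different class ratios.
#'
#' @param d a `labeled_dataset` (needs a `label` column with both classes).
#' @param seed integer seed for the resampling.
#' @return the rebalanced `labeled_dataset`.
#' @export
oversample_minority <- function(d, seed = 1L) {
  counts <- table(factor(d$label, levels = c(0, 1)))
  if (any(counts == 0)) abort_parameter("both classes must be present")
  minority <- as.integer(names(counts)[which.min(counts)])
  deficit <- abs(diff(as.vector(counts)))
  if (deficit == 0) {
    return(d)
  }
  idx <- which(d$label == minority)
  # sample.int guards the length-1 idx case
  extra <- idx[withr::with_seed(seed, sample.int(length(idx), deficit, replace = TRUE))]
  out <- dplyr::bind_rows(as_tibble(d), as_tibble(d)[extra, , drop = FALSE])
  structure(out,
    class = class(d),
    window_s = attr(d, "window_s"), subject_id = attr(d, "subject_id")
  )
}

#' Class balance of a labeled dataset
#'
#' @param d a `labeled_dataset`.
#' @return tibble with per-class counts and fractions.
#' @export
class_balance <- function(d) {
  tb <- table(factor(d$label, levels = c(0, 1)))
  tibble(
    label = c(0L, 1L), n = as.vector(tb),
    fraction = as.vector(tb) / sum(tb)
  )
}
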