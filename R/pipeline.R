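# End-to-end glue: raw per-session streams -> preprocessed streams ->
# fused feature matrix -> labeled per-subject datasets.

#' Default preprocessing configuration
#'
#' Cutoffs follow the published processing chain where realizable: 10 Hz
#' low-pass for the 32 Hz wrist acceleration, 1-8 Hz band-pass for the
#' 64 Hz blood volume pulse, k = 20 nearest-neighbour imputation for the
#' face/head channels. The motion stream samples at 15 Hz (Nyquist
#' 7.5 Hz), so its low-pass cutoff defaults to 6 Hz.
#'
#' @param wings_lowpass_hz,e4_lowpass_hz,bvp_band_hz,impute_k,hr_window_s,
#'   al_window_s,eda_tonic_cutoff_hz,max_bridge_gap tunables; see the
#'   stage functions.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(wings_lowpass_hz = 6,
                            e4_lowpass_hz = 10,
                            bvp_band_hz = c(1, 8),
                            impute_k = 20,
                            hr_window_s = 10,
                            al_window_s = 1,
                            eda_tonic_cutoff_hz = 0.05,
                            max_bridge_gap = 2) {
  structure(as.list(environment()), class = "pipeline_config")
}

# fill residual NAs only for filtering, then restore them, so excluded
# rows stay excluded downstream while the filter sees a complete signal
filter_with_na_guard <- function(s, f) {
  chans <- stream_channels(s)
  na_map <- purrr::map(rlang::set_names(chans), function(ch) which(is.na(s[[ch]])))
  if (any(lengths(na_map) > 0)) {
    s <- impute_numeric(s, k = 4)
  }
  s <- f(s)
  for (ch in chans) s[[ch]][na_map[[ch]]] <- NA_real_
  s
}

#' Preprocess one session's raw streams
#'
#' WINGS: corruption scrub, linear bridging of gaps up to 2 samples,
#' zero-phase low-pass (residual unbridgeable rows stay missing and are
#' excluded from the feature timeline). BVP: 1-8 Hz band-pass, then heart
#' rate from inter-beat intervals. EDA: tonic/phasic decomposition. Wrist
#' acceleration: 10 Hz low-pass. Kinect: numeric imputation for head
#' rotations, modal imputation for facial scores.
#'
#' @param streams named list with `wings`, `bvp`, `eda`, `e4_acc`,
#'   `kinect` [sensor_stream()]s (any may be `NULL`).
#' @param config a [pipeline_config()].
#' @return list with processed inputs for [build_feature_matrix()] plus
#'   the WINGS `corruption_report`.
#' @export
preprocess_session <- function(streams, config = pipeline_config()) {
  out <- list()
  if (!is.null(streams$wings)) {
    sc <- scrub_corrupted(streams$wings)
    w <- bridge_gaps(sc$stream, max_gap = config$max_bridge_gap)
    w <- filter_with_na_guard(w, function(s) {
      lowpass_filter(s, config$wings_lowpass_hz)
    })
    out$wings <- w
    out$corruption_report <- sc$report
  }
  if (!is.null(streams$bvp)) {
    b <- bandpass_filter(streams$bvp, config$bvp_band_hz[1], config$bvp_band_hz[2])
    out$hr <- heart_rate_from_bvp(b, window_s = config$hr_window_s)
    # bridge sparse unreliable windows so fusion always has a value
    if (anyNA(out$hr$hr_bpm) && !all(is.na(out$hr$hr_bpm))) {
      out$hr$hr_bpm <- approx(
        out$hr$timestamp_ms[!is.na(out$hr$hr_bpm)],
        out$hr$hr_bpm[!is.na(out$hr$hr_bpm)],
        xout = out$hr$timestamp_ms, rule = 2
      )$y
    }
  }
  if (!is.null(streams$eda)) {
    out$eda_feat <- eda_decompose(streams$eda,
      tonic_cutoff_hz = config$eda_tonic_cutoff_hz
    )
  }
  if (!is.null(streams$e4_acc)) {
    out$e4_acc <- lowpass_filter(streams$e4_acc, config$e4_lowpass_hz)
  }
  if (!is.null(streams$kinect)) {
    k <- streams$kinect
    head_ch <- intersect(c("head_roll", "head_pitch", "head_yaw"), stream_channels(k))
    face_ch <- grep("^face_", stream_channels(k), value = TRUE)
    k <- impute_numeric(k, k = config$impute_k, channels = head_ch)
    k <- impute_categorical(k, k = config$impute_k, channels = face_ch)
    out$kinect <- k
  }
  out
}

#' Feature matrices and logs for a whole synthetic subject
#'
#' @param subject a `synthetic_subject` from [generate_subject()].
#' @param config a [pipeline_config()].
#' @param feature_set `"strict"` (32 features) or `"extended"`.
#' @return list with `fms` (per-session `feature_matrix`), `logs`
#'   (per-session [event_log()]s) and `corruption` reports.
#' @export
subject_features <- function(subject, config = pipeline_config(),
                             feature_set = "strict") {
  res <- purrr::map(subject$sessions, function(s) {
    pp <- preprocess_session(s$streams, config)
    fm <- build_feature_matrix(pp$wings,
      hr = pp$hr, eda_feat = pp$eda_feat,
      e4_acc = pp$e4_acc, kinect = pp$kinect,
      feature_set = feature_set, al_window_s = config$al_window_s
    )
    list(fm = fm, log = s$log, corruption = pp$corruption_report)
  })
  list(
    fms = purrr::map(res, "fm"),
    logs = purrr::map(res, "log"),
    corruption = purrr::map(res, "corruption")
  )
}

#' Labeled per-subject dataset from a synthetic subject
#'
#' Processes every session, labels each on its own session clock, and
#' binds the rows into one `labeled_dataset`.
#'
#' @inheritParams subject_features
#' @param window_s labeling window W in seconds (default 90).
#' @return a `labeled_dataset` with the subject id attached.
#' @export
subject_dataset <- function(subject, window_s = 90,
                            config = pipeline_config(),
                            feature_set = "strict") {
  sf <- subject_features(subject, config, feature_set)
  labeled <- purrr::map2(sf$fms, sf$logs, function(fm, lg) {
    # control sessions legitimately have no precursors; keep quiet here
    as_tibble(suppressWarnings(assign_labels(fm, lg, window_s = window_s)))
  })
  structure(list_rbind(labeled),
    class = c("labeled_dataset", class(tibble())),
    window_s = window_s, subject_id = subject$subject_id
  )
}

#' Labeled datasets for a whole cohort
#'
#' @param cohort list of `synthetic_subject`s from [generate_cohort()].
#' @inheritParams subject_dataset
#' @return named list of `labeled_dataset`s.
#' @export
cohort_datasets <- function(cohort, window_s = 90,
                            config = pipeline_config(),
                            feature_set = "strict") {
  purrr::map(cohort, subject_dataset,
    window_s = window_s,
    config = config, feature_set = feature_set
  )
}

#' Window-sensitivity analysis across a subject's sessions
#'
#' Relabels every session at each window, binds the sessions, oversamples
#' to 1:1 and cross-validates — the per-visit version of
#' [window_sensitivity()].
#'
#' @param fms list of per-session feature matrices.
#' @param logs list of matching event logs.
#' @inheritParams window_sensitivity
#' @return an `escalert_windows` object.
#' @export
window_sensitivity_visit <- function(fms, logs, windows = c(30, 60, 90, 120),
                                     algorithm = "rf", k = 5, seed = 1L, ...) {
  if (any(windows <= 0)) abort_parameter("windows must be > 0")
  rows <- purrr::map(windows, function(w) {
    labeled <- purrr::map2(fms, logs, function(fm, lg) {
      as_tibble(suppressWarnings(assign_labels(fm, lg, window_s = w)))
    })
    d <- structure(list_rbind(labeled),
      class = c("labeled_dataset", class(tibble())), window_s = w
    )
    d <- oversample_minority(d, seed = seed)
    cv <- crossval_individual(d, algorithm, k = k, seed = seed, ...)
    tibble(window_s = w, accuracy = cv$accuracy, n = cv$n)
  }) |> list_rbind()
  structure(
    list(results = rows, algorithm = algorithm, k = k, seed = seed),
    class = "escalert_windows"
  )
}
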