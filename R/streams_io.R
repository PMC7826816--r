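# Tabular sensor-stream and behavioral event-log I/O.
#
# On-disk dialect: UTF-8, tab-separated, header row, integer millisecond
# timestamps since session start, literal "NA" as the missing marker.
# One file per modality per session (`<session>_<modality>.tsv`, columns
# `timestamp_ms, <channel...>`) plus one event log per session
# (`<session>_events.tsv`, columns `timestamp_ms, event_kind`).

EVENT_KINDS <- c(
  "session_start", "EO_on", "SR_on", "calm_on", "calm_off",
  "precursor", "problem_behavior", "session_end"
)

#' Construct a sensor stream
#'
#' A sensor stream is a tibble with a `timestamp_ms` column (strictly
#' increasing integer milliseconds since session start) and one numeric
#' column per channel, carrying the modality name, nominal sampling rate
#' and per-channel units as attributes. Missing samples are `NA`.
#'
#' @param data data frame with `timestamp_ms` plus channel columns.
#' @param modality modality label, e.g. `"wings"`, `"bvp"`, `"eda"`,
#'   `"e4_acc"`, `"kinect"`.
#' @param nominal_rate_hz nominal sampling rate in Hz (> 0).
#' @param units optional named character vector of per-channel unit labels.
#' @param validate check invariants (strictly increasing timestamps, rate
#'   consistency) and error on violation.
#' @return a `sensor_stream` tibble.
#' @export
sensor_stream <- function(data, modality, nominal_rate_hz, units = NULL,
                          validate = TRUE) {
  df <- as_tibble(data)
  if (!"timestamp_ms" %in% names(df)) {
    abort_schema("sensor stream needs a `timestamp_ms` column")
  }
  df <- dplyr::relocate(df, "timestamp_ms")
  out <- structure(df,
    class = c("sensor_stream", class(df)),
    modality = modality,
    nominal_rate_hz = nominal_rate_hz,
    units = units
  )
  if (validate) validate_stream(out)
  out
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf(
    "<sensor_stream> modality=%s rate=%g Hz channels=%d samples=%d\n",
    stream_modality(x), stream_rate(x), length(stream_channels(x)), nrow(x)
  ))
  NextMethod()
}

#' @rdname sensor_stream
#' @param x a `sensor_stream`.
#' @export
stream_channels <- function(x) setdiff(names(x), "timestamp_ms")

#' @rdname sensor_stream
#' @export
stream_rate <- function(x) attr(x, "nominal_rate_hz")

#' @rdname sensor_stream
#' @export
stream_modality <- function(x) attr(x, "modality")

#' Validate sensor-stream invariants
#'
#' Checks strictly increasing timestamps, a positive nominal rate, and that
#' the median inter-sample interval is within 20% of `1000 / nominal_rate`.
#'
#' @param x a `sensor_stream`.
#' @return `x`, invisibly; errors (class `escalert_format_error`) otherwise.
#' @export
validate_stream <- function(x) {
  ts <- x$timestamp_ms
  rate <- stream_rate(x)
  if (is.null(rate) || !is.finite(rate) || rate <= 0) {
    abort_format("nominal_rate_hz must be > 0")
  }
  if (anyNA(ts)) abort_format("timestamps must not be missing")
  bad <- which(diff(ts) <= 0)
  if (length(bad)) {
    abort_format(sprintf(
      "timestamps not strictly increasing at row(s) %s",
      paste(head(bad + 1L, 5L), collapse = ", ")
    ))
  }
  if (length(ts) >= 3L) {
    expected <- 1000 / rate
    got <- median(diff(ts))
    if (abs(got - expected) > 0.2 * expected) {
      abort_format(sprintf(
        "median inter-sample interval %.2f ms is not within 20%% of nominal %.2f ms",
        got, expected
      ))
    }
  }
  invisible(x)
}

#' Describe the expected layout of a stream file
#'
#' @param modality modality label.
#' @param channels character vector of required channel names.
#' @param nominal_rate_hz nominal rate in Hz.
#' @param units optional named units.
#' @return a `stream_schema` list.
#' @export
stream_schema <- function(modality, channels, nominal_rate_hz, units = NULL) {
  structure(
    list(
      modality = modality, channels = channels,
      nominal_rate_hz = nominal_rate_hz, units = units
    ),
    class = "stream_schema"
  )
}

#' Built-in stream schemas for the five modalities
#'
#' `wings` is the 7-IMU motion garment (15 Hz; per-IMU accelerometer and
#' magnetometer triplets for both forearms, both upper arms and three back
#' positions), `bvp` blood volume pulse (64 Hz), `eda` electrodermal
#' activity (4 Hz), `e4_acc` wrist acceleration (32 Hz) and `kinect`
#' head rotations plus discrete facial-expression scores (10 Hz).
#'
#' @param modality one of `"wings"`, `"bvp"`, `"eda"`, `"e4_acc"`, `"kinect"`.
#' @return a [stream_schema()].
#' @export
default_schema <- function(modality = c("wings", "bvp", "eda", "e4_acc", "kinect")) {
  modality <- match.arg(modality)
  switch(modality,
    wings = stream_schema(
      "wings",
      as.vector(t(outer(WINGS_IMUS, c("acclx", "accly", "acclz", "magx", "magy", "magz"),
        paste,
        sep = "_"
      ))),
      15
    ),
    bvp = stream_schema("bvp", "bvp", 64),
    eda = stream_schema("eda", "eda_us", 4, c(eda_us = "microsiemens")),
    e4_acc = stream_schema("e4_acc", c("ax", "ay", "az"), 32,
      c(ax = "g", ay = "g", az = "g")
    ),
    kinect = stream_schema(
      "kinect",
      c(
        "head_roll", "head_pitch", "head_yaw",
        "face_happy", "face_engaged", "face_lookaway",
        "face_eyes_closed", "face_mouth_open"
      ),
      10
    )
  )
}

# the seven IMU positions: forearms, upper arms, three back locations
WINGS_IMUS <- c("lfa", "rfa", "lua", "rua", "bk1", "bk2", "bk3")

#' Read a sensor stream from a tab-separated file
#'
#' Unparseable rows (wrong field count, non-numeric values where numbers are
#' required) are counted, reported via a warning and the `n_bad_rows`
#' attribute, and excluded — never silently dropped.
#'
#' @param path file path.
#' @param schema a [stream_schema()] naming the required channels and rate.
#' @return a validated [sensor_stream()].
#' @export
read_stream <- function(path, schema) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_double()),
    na = "NA", progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(df)
  n_bad <- 0L
  if (nrow(probs)) {
    bad_lines <- unique(probs$row) # physical file lines (header is line 1)
    n_bad <- length(bad_lines)
    warning(sprintf(
      "%s: %d unparseable row(s) dropped (first at line %d)",
      path, n_bad, min(bad_lines)
    ), call. = FALSE)
    df <- df[-(bad_lines - 1L), , drop = FALSE]
  }
  missing_ch <- setdiff(c("timestamp_ms", schema$channels), names(df))
  if (length(missing_ch)) {
    abort_schema(sprintf(
      "%s: missing required column(s): %s",
      path, paste(missing_ch, collapse = ", ")
    ))
  }
  df <- df[, c("timestamp_ms", schema$channels)]
  out <- sensor_stream(df, schema$modality, schema$nominal_rate_hz,
    units = schema$units
  )
  attr(out, "n_bad_rows") <- n_bad
  out
}

#' Write a sensor stream to a tab-separated file
#'
#' @param x a `sensor_stream`.
#' @param path destination path; written atomically (write-then-rename).
#' @return `path`, invisibly.
#' @export
write_stream <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(as_tibble(x), tmp, na = "NA", progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Construct a behavioral event log
#'
#' An event log is a tibble with columns `timestamp_ms` (non-decreasing)
#' and `event_kind` (one of `session_start`, `EO_on`, `SR_on`, `calm_on`,
#' `calm_off`, `precursor`, `problem_behavior`, `session_end`), carrying
#' the session id and type (`control` or `test`) as attributes.
#'
#' @param entries data frame with `timestamp_ms` and `event_kind` columns.
#' @param session_id session label.
#' @param session_type `"control"` or `"test"`.
#' @param validate check event-log invariants.
#' @return an `event_log` tibble.
#' @export
event_log <- function(entries, session_id, session_type = c("test", "control"),
                      validate = TRUE) {
  session_type <- match.arg(session_type)
  df <- as_tibble(entries)[, c("timestamp_ms", "event_kind")]
  out <- structure(df,
    class = c("event_log", class(df)),
    session_id = session_id, session_type = session_type
  )
  if (validate) validate_event_log(out)
  out
}

#' @rdname event_log
#' @param x an `event_log`.
#' @export
log_session_type <- function(x) attr(x, "session_type")

#' @rdname event_log
#' @export
log_session_id <- function(x) attr(x, "session_id")

#' Validate event-log invariants
#'
#' Timestamps non-decreasing; first entry `session_start`, last
#' `session_end`; `calm_on`/`calm_off` strictly alternating;
#' `EO_on`/`SR_on` strictly alternating after the first condition; control
#' sessions contain no `EO_on` at all. Every failure names the offending
#' timestamps.
#'
#' @param x an `event_log`.
#' @return `x` invisibly; errors with class `escalert_validation_error`.
#' @export
validate_event_log <- function(x) {
  if (nrow(x) == 0L) abort_format("empty event log")
  bad_kind <- setdiff(unique(x$event_kind), EVENT_KINDS)
  if (length(bad_kind)) {
    abort_format(sprintf("unknown event kind(s): %s", paste(bad_kind, collapse = ", ")))
  }
  if (any(diff(x$timestamp_ms) < 0)) {
    i <- which(diff(x$timestamp_ms) < 0)[1]
    abort_format(sprintf(
      "timestamps decrease at t=%d -> t=%d",
      x$timestamp_ms[i], x$timestamp_ms[i + 1]
    ))
  }
  if (x$event_kind[1] != "session_start") {
    abort_validation("first entry must be session_start")
  }
  if (x$event_kind[nrow(x)] != "session_end") {
    abort_validation("last entry must be session_end")
  }
  calm <- x[x$event_kind %in% c("calm_on", "calm_off"), ]
  if (nrow(calm)) {
    expected <- rep(c("calm_on", "calm_off"), length.out = nrow(calm))
    bad <- which(calm$event_kind != expected)
    if (length(bad)) {
      abort_validation(sprintf(
        "calm_on/calm_off do not alternate at t=%s",
        paste(calm$timestamp_ms[bad], collapse = ", ")
      ))
    }
  }
  cond <- x[x$event_kind %in% c("EO_on", "SR_on"), ]
  if (log_session_type(x) == "control" && any(cond$event_kind == "EO_on")) {
    abort_validation(sprintf(
      "control sessions contain only S^R conditions; EO_on at t=%s",
      paste(cond$timestamp_ms[cond$event_kind == "EO_on"], collapse = ", ")
    ))
  }
  if (nrow(cond) >= 2L) {
    rep_i <- which(cond$event_kind[-1] == cond$event_kind[-nrow(cond)])
    if (length(rep_i)) {
      abort_validation(sprintf(
        "EO_on/SR_on must alternate; repeated %s at t=%s",
        cond$event_kind[rep_i[1] + 1],
        paste(cond$timestamp_ms[rep_i + 1], collapse = ", ")
      ))
    }
  }
  invisible(x)
}

#' Read a behavioral event log
#'
#' @param path tab-separated file with columns `timestamp_ms`, `event_kind`.
#' @param session_id session label (defaults to the file stem).
#' @param session_type `"test"` or `"control"`.
#' @return a validated [event_log()].
#' @export
read_event_log <- function(path, session_id = NULL,
                           session_type = c("test", "control")) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  if (file.size(path) == 0L) abort_format(sprintf("empty file: %s", path))
  session_type <- match.arg(session_type)
  if (is.null(session_id)) {
    session_id <- sub("_events$", "", tools::file_path_sans_ext(basename(path)))
  }
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      timestamp_ms = readr::col_double(),
      event_kind = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (!all(c("timestamp_ms", "event_kind") %in% names(df))) {
    abort_format(sprintf("%s: expected columns timestamp_ms, event_kind", path))
  }
  event_log(df, session_id = session_id, session_type = session_type)
}

#' Write a behavioral event log
#'
#' @param x an `event_log`.
#' @param path destination path; written atomically.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(as_tibble(x), tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read or write a session manifest
#'
#' A manifest is a small YAML file listing, per session, the subject id,
#' session id, session type, the per-modality stream files and the event
#' log file, so a directory of TSVs is self-describing.
#'
#' @param path YAML manifest path.
#' @return for `read_session_manifest`, a tibble with one row per session.
#' @export
read_session_manifest <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  m <- yaml::read_yaml(path)
  purrr::map(m$sessions, function(s) {
    tibble(
      subject_id = m$subject_id %||% s$subject_id,
      session_id = s$session_id,
      session_type = s$session_type,
      events_file = s$events_file,
      streams = list(s$streams)
    )
  }) |> list_rbind()
}

#' @rdname read_session_manifest
#' @param sessions tibble as returned by `read_session_manifest`.
#' @param subject_id subject label stored at the top level.
#' @export
write_session_manifest <- function(sessions, path, subject_id = NULL) {
  m <- list(
    subject_id = subject_id,
    sessions = purrr::pmap(sessions, function(session_id, session_type,
                                              events_file, streams, ...) {
      list(
        session_id = session_id, session_type = session_type,
        events_file = events_file, streams = streams
      )
    })
  )
  tmp <- paste0(path, ".tmp")
  yaml::write_yaml(m, tmp)
  file.rename(tmp, path)
  invisible(path)
}
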