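# Per-modality signal conditioning: zero-phase Butterworth filtering,
# corruption scrubbing, and nearest-neighbour imputation for the face/head
# tracking channels.
#
# Filters are 4th-order Butterworth applied forward-backward
# (signal::filtfilt), i.e. zero phase: features are aligned against
# millisecond behavioral timestamps, and a causal filter's group delay
# would shift every feature relative to its label.

butter_filtfilt <- function(x, rate, type, cutoff_hz, order) {
  w <- cutoff_hz / (rate / 2)
  filt <- signal::butter(order, w, type = type)
  if (type == "low") {
    # unit DC gain: filtering the mean-centered signal and restoring the
    # mean avoids start-up transients at low normalized cutoffs
    m <- mean(x)
    as.numeric(signal::filtfilt(filt, x - m)) + m
  } else {
    as.numeric(signal::filtfilt(filt, x))
  }
}

check_filter_input <- function(s, cutoffs) {
  rate <- stream_rate(s)
  if (any(cutoffs >= rate / 2)) {
    abort_parameter(sprintf(
      "cutoff %g Hz is not below the Nyquist frequency %g Hz",
      max(cutoffs), rate / 2
    ))
  }
  vals <- as_tibble(s)[stream_channels(s)]
  if (anyNA(vals)) {
    abort_parameter("stream has missing values; scrub/impute before filtering")
  }
  rate
}

#' Low-pass filter a stream
#'
#' Zero-phase Butterworth low-pass applied to every channel; timestamps are
#' unchanged. Used with a 10 Hz cutoff on the 32 Hz wrist acceleration.
#'
#' @param s a [sensor_stream()] at a regular rate with no missing values.
#' @param cutoff_hz cutoff frequency in Hz, below Nyquist.
#' @param order filter order (default 4).
#' @param channels channels to filter (default all).
#' @return the filtered `sensor_stream`.
#' @export
lowpass_filter <- function(s, cutoff_hz, order = 4, channels = stream_channels(s)) {
  rate <- check_filter_input(s, cutoff_hz)
  for (ch in channels) s[[ch]] <- butter_filtfilt(s[[ch]], rate, "low", cutoff_hz, order)
  s
}

#' Band-pass filter a stream
#'
#' Zero-phase Butterworth band-pass; removes DC and drift while preserving
#' the mid-band. Used with a 1-8 Hz band on the 64 Hz blood-volume-pulse
#' signal before beat detection.
#'
#' @param s a [sensor_stream()] with no missing values.
#' @param low_hz,high_hz band edges in Hz, `0 < low < high < rate/2`.
#' @param order filter order per pass (default 4).
#' @param channels channels to filter (default all).
#' @return the filtered `sensor_stream`.
#' @export
bandpass_filter <- function(s, low_hz, high_hz, order = 4,
                            channels = stream_channels(s)) {
  if (!(low_hz > 0 && low_hz < high_hz)) {
    abort_parameter("need 0 < low_hz < high_hz")
  }
  rate <- check_filter_input(s, c(low_hz, high_hz))
  for (ch in channels) {
    s[[ch]] <- butter_filtfilt(s[[ch]], rate, "pass", c(low_hz, high_hz), order)
  }
  s
}

# indices of the k nearest available samples (by |timestamp difference|)
# around one query time; avail_t sorted increasing
k_nearest_available <- function(t, avail_t, k) {
  n <- length(avail_t)
  k <- min(k, n)
  pos <- findInterval(t, avail_t)
  lo <- max(1L, pos - k + 1L)
  hi <- min(n, pos + k)
  cand <- lo:hi
  ord <- order(abs(avail_t[cand] - t), avail_t[cand]) # ties -> earlier sample
  cand[ord[seq_len(k)]]
}

#' Impute missing numeric samples from the k timestamp-closest neighbours
#'
#' Each missing entry of a channel is replaced by the mean of the `k`
#' available samples of that channel closest in time (either side); when
#' fewer than `k` are available, all of them are used. Matches the head
#' rotation imputation rule. Non-missing values are never altered.
#'
#' @param s a [sensor_stream()].
#' @param k neighbour count (default 20).
#' @param channels channels to impute (default all).
#' @return the stream with no missing values in `channels`.
#' @export
impute_numeric <- function(s, k = 20, channels = stream_channels(s)) {
  ts <- s$timestamp_ms
  for (ch in channels) {
    x <- s[[ch]]
    miss <- which(is.na(x))
    if (!length(miss)) next
    avail <- which(!is.na(x))
    if (!length(avail)) abort_parameter(sprintf("channel %s is entirely missing", ch))
    s[[ch]][miss] <- vapply(miss, function(i) {
      nb <- avail[k_nearest_available(ts[i], ts[avail], k)]
      mean(x[nb])
    }, numeric(1))
  }
  s
}

#' Impute missing categorical scores from the k timestamp-closest neighbours
#'
#' Each missing entry is replaced by the most frequent value among the `k`
#' closest available samples (matching the facial-expression imputation
#' rule for the discrete 0 / 0.5 / 1 scores); frequency ties are broken in
#' favour of the value of the single nearest-in-time sample.
#'
#' @inheritParams impute_numeric
#' @return the stream with no missing values in `channels`; imputed values
#'   are always existing score values.
#' @export
impute_categorical <- function(s, k = 20, channels = stream_channels(s)) {
  ts <- s$timestamp_ms
  for (ch in channels) {
    x <- s[[ch]]
    miss <- which(is.na(x))
    if (!length(miss)) next
    avail <- which(!is.na(x))
    if (!length(avail)) abort_parameter(sprintf("channel %s is entirely missing", ch))
    s[[ch]][miss] <- vapply(miss, function(i) {
      nb <- avail[k_nearest_available(ts[i], ts[avail], k)] # nearest first
      counts <- table(x[nb])
      top <- names(counts)[counts == max(counts)]
      if (length(top) > 1L) {
        # tie: first neighbour is the nearest in time; take the first tied
        # class encountered walking outward
        as.numeric(x[nb][match(TRUE, as.character(x[nb]) %in% top)])
      } else {
        as.numeric(top)
      }
    }, numeric(1))
  }
  s
}

#' Scrub corrupted rows to missing and report per-channel fractions
#'
#' Non-finite values, and acceleration magnitudes beyond the IMU full-scale
#' range, are marked missing. Nothing is dropped; downstream stages decide
#' whether to bridge or exclude.
#'
#' @param s a [sensor_stream()].
#' @param accel_limit_g absolute plausibility limit for channels whose name
#'   contains `accl`/`ax`/`ay`/`az` (default 16 g, the IMU full scale).
#' @return a list with `stream` (scrubbed) and `report`, a tibble of
#'   per-channel corrupted counts and fractions.
#' @export
scrub_corrupted <- function(s, accel_limit_g = 16) {
  chans <- stream_channels(s)
  rep_list <- purrr::map(chans, function(ch) {
    x <- s[[ch]]
    # NaN is a corruption artifact, a plain NA is already-missing
    bad <- is.nan(x) | (!is.na(x) & !is.finite(x))
    if (grepl("(^|_)(accl[xyz]|a[xyz])$", ch)) {
      bad <- bad | (!is.na(x) & is.finite(x) & abs(x) > accel_limit_g)
    }
    s[[ch]][bad] <<- NA_real_
    tibble(
      channel = ch, n_corrupted = sum(bad),
      fraction = sum(bad) / length(x)
    )
  })
  list(stream = s, report = list_rbind(rep_list))
}

#' Linearly bridge short missing gaps
#'
#' Interior missing runs of at most `max_gap` samples are filled by linear
#' interpolation against timestamps; longer runs (and leading/trailing
#' missingness) are left missing. Used for scrubbed IMU rows, which are
#' rare (< 0.3%) and almost always isolated.
#'
#' @param s a [sensor_stream()].
#' @param max_gap longest run length to bridge (default 2 samples).
#' @param channels channels to bridge (default all).
#' @return the stream with short gaps filled.
#' @export
bridge_gaps <- function(s, max_gap = 2, channels = stream_channels(s)) {
  ts <- s$timestamp_ms
  for (ch in channels) {
    x <- s[[ch]]
    if (!anyNA(x) || all(is.na(x))) next
    r <- rle(is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths <= max_gap)) {
      i0 <- starts[j]
      i1 <- ends[j]
      if (i0 == 1L || i1 == length(x)) next # no anchor on one side
      fill <- approx(
        x = ts[c(i0 - 1L, i1 + 1L)], y = x[c(i0 - 1L, i1 + 1L)],
        xout = ts[i0:i1]
      )$y
      x[i0:i1] <- fill
    }
    s[[ch]] <- x
  }
  s
}
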