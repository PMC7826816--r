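# Per-modality feature extraction and nearest-in-time fusion onto the
# 15 Hz movement timeline.
#
# The fused vector has 32 features in the default ("paper-strict") set:
# 20 motion features (roll, pitch, yaw, activity level for left/right
# forearm, left/right upper arm and torso), heart rate (bpm), tonic SCL
# and phasic SCR (microsiemens), the three wrist acceleration axes (g),
# and 6 face/head features (head roll/pitch/yaw in degrees plus the
# happy / engaged / looking-away scores). The eyes-closed and mouth-open
# scores are available through `kinect_scores`.

#' Activity level: mean acceleration magnitude
#'
#' `AL = mean(sqrt(ax^2 + ay^2 + az^2))` over a window of samples — the
#' physical movement intensity. With `strict_divisor` the sum is divided
#' by the constant 7 instead of the sample count (a printed variant of the
#' formula); this only rescales the feature.
#'
#' @param ax,ay,az acceleration components over the window, in g.
#' @param strict_divisor divide by 7 instead of the sample count.
#' @return the activity level, a single number (g).
#' @export
activity_level <- function(ax, ay, az, strict_divisor = FALSE) {
  n <- length(ax)
  if (n == 0L) abort_parameter("empty window")
  mags <- sqrt(ax^2 + ay^2 + az^2)
  if (strict_divisor) sum(mags) / 7 else sum(mags) / n
}

# trailing-window rolling AL on a regular-rate stream, one value per sample
rolling_activity_level <- function(ax, ay, az, rate, window_s = 1,
                                   strict_divisor = FALSE) {
  mags <- sqrt(ax^2 + ay^2 + az^2)
  w <- max(1L, round(window_s * rate))
  cs <- cumsum(c(0, mags))
  n <- length(mags)
  i0 <- pmax(seq_len(n) - w, 0L)
  sums <- cs[seq_len(n) + 1L] - cs[i0 + 1L]
  if (strict_divisor) sums / 7 else sums / (seq_len(n) - i0)
}

#' Heart rate from blood-volume-pulse inter-beat intervals
#'
#' Detects systolic peaks on the band-passed BVP signal (local maxima with
#' a refractory distance corresponding to 210 bpm and an adaptive height
#' threshold), forms inter-beat intervals (IBI), and reports
#' `HR = 60 / mean(IBI)` in bpm over a trailing window, one value per
#' second. Windows with fewer than two peaks give a missing value.
#'
#' @param bvp a band-passed [sensor_stream()] with a `bvp` channel (64 Hz).
#' @param window_s trailing IBI-averaging window in seconds (default 10).
#' @param plausible_bpm HR values outside this range are flagged missing.
#' @return tibble with `timestamp_ms` (1 Hz grid) and `hr_bpm`.
#' @export
heart_rate_from_bvp <- function(bvp, window_s = 10, plausible_bpm = c(20, 250)) {
  rate <- stream_rate(bvp)
  x <- bvp$bvp
  min_dist <- max(1L, floor(rate * 60 / 210))
  thr <- 0.3 * stats::quantile(x[x > 0], 0.9, na.rm = TRUE, names = FALSE)
  if (!is.finite(thr) || thr <= 0) thr <- .Machine$double.eps
  pk <- pracma::findpeaks(x,
    minpeakheight = thr, minpeakdistance = min_dist, zero = "0"
  )
  peak_t <- if (is.null(pk)) numeric(0) else sort(bvp$timestamp_ms[pk[, 2]])
  t_end <- max(bvp$timestamp_ms)
  grid <- seq(0, t_end, by = 1000)
  hr <- vapply(grid, function(t) {
    in_w <- peak_t[peak_t > t - window_s * 1000 & peak_t <= t]
    if (length(in_w) < 2L) {
      return(NA_real_)
    }
    60 / mean(diff(in_w) / 1000)
  }, numeric(1))
  hr[!is.na(hr) & (hr < plausible_bpm[1] | hr > plausible_bpm[2])] <- NA_real_
  tibble(timestamp_ms = grid, hr_bpm = hr)
}

#' Decompose electrodermal activity into tonic and phasic components
#'
#' The tonic skin conductance level (SCL) is a zero-phase low-pass of the
#' signal (default cutoff 0.05 Hz); the phasic skin conductance response
#' (SCR) is the residual, so `SCL + SCR` reconstructs the input exactly.
#'
#' @param eda a [sensor_stream()] with an `eda_us` channel (4 Hz),
#'   non-negative after scrubbing.
#' @param tonic_cutoff_hz SCL low-pass cutoff in Hz.
#' @param order filter order (default 2; the very low normalized cutoff
#'   makes higher orders numerically fragile).
#' @return tibble with `timestamp_ms`, `scl_us`, `scr_us`.
#' @export
eda_decompose <- function(eda, tonic_cutoff_hz = 0.05, order = 2) {
  x <- eda$eda_us
  if (anyNA(x)) abort_parameter("EDA has missing values; scrub/impute first")
  if (any(x < 0)) abort_parameter("negative skin conductance after scrubbing")
  scl <- butter_filtfilt(x, stream_rate(eda), "low", tonic_cutoff_hz, order)
  tibble(timestamp_ms = eda$timestamp_ms, scl_us = scl, scr_us = x - scl)
}

# fuse one feature table onto base timestamps by the nearest-in-time rule
fuse_nearest <- function(base_ts, feat, cols = setdiff(names(feat), "timestamp_ms")) {
  keep <- !is.na(feat$timestamp_ms) & rowSums(is.na(feat[cols])) < length(cols)
  feat <- feat[keep, , drop = FALSE]
  if (!nrow(feat)) abort_parameter("no available samples to fuse")
  idx <- nearest_index(base_ts, feat$timestamp_ms)
  feat[idx, cols, drop = FALSE]
}

#' Fuse all processed modalities into the per-instant feature matrix
#'
#' Takes the 15 Hz motion stream as the timeline basis: one output row per
#' motion sample. Motion features (per-segment roll/pitch/yaw in degrees
#' and activity level) are computed from the IMU channels; every other
#' modality contributes the value of its timestamp-closest sample (ties
#' go to the earlier sample) — values are carried verbatim, never
#' interpolated, at the fusion stage.
#'
#' @param wings preprocessed WINGS [sensor_stream()] (15 Hz, 7 IMUs); rows
#'   still missing after bridging are dropped from the timeline.
#' @param hr tibble from [heart_rate_from_bvp()].
#' @param eda_feat tibble from [eda_decompose()].
#' @param e4_acc preprocessed wrist acceleration [sensor_stream()].
#' @param kinect imputed Kinect [sensor_stream()].
#' @param feature_set `"strict"` for the 32-feature set, `"extended"` to
#'   add the eyes-closed / mouth-open scores.
#' @param al_window_s activity-level window in seconds (default 1).
#' @param require_all error if a modality is missing (`TRUE`, the default)
#'   or drop its columns with a warning.
#' @return a `feature_matrix` tibble: `timestamp_ms` plus feature columns,
#'   no missing entries.
#' @export
build_feature_matrix <- function(wings, hr = NULL, eda_feat = NULL,
                                 e4_acc = NULL, kinect = NULL,
                                 feature_set = c("strict", "extended"),
                                 al_window_s = 1, require_all = TRUE) {
  feature_set <- match.arg(feature_set)
  wf <- wings_features(wings, al_window_s = al_window_s)
  base_ts <- wf$timestamp_ms
  out <- list(wf)
  fuse_or_handle <- function(feat, what, cols) {
    if (is.null(feat)) {
      if (require_all) abort_parameter(sprintf("modality '%s' is absent", what))
      warning(sprintf("modality '%s' absent; columns dropped", what), call. = FALSE)
      return(NULL)
    }
    fuse_nearest(base_ts, as_tibble(feat), cols)
  }
  out$hr <- fuse_or_handle(hr, "heart rate", "hr_bpm")
  out$eda <- fuse_or_handle(eda_feat, "eda", c("scl_us", "scr_us"))
  if (!is.null(e4_acc)) {
    acc <- as_tibble(e4_acc) |> rename(wrist_ax = "ax", wrist_ay = "ay", wrist_az = "az")
    out$acc <- fuse_nearest(base_ts, acc, c("wrist_ax", "wrist_ay", "wrist_az"))
  } else {
    out$acc <- fuse_or_handle(NULL, "wrist acceleration", character())
  }
  kin_cols <- c(
    "head_roll", "head_pitch", "head_yaw",
    "face_happy", "face_engaged", "face_lookaway"
  )
  if (feature_set == "extended") {
    kin_cols <- c(kin_cols, "face_eyes_closed", "face_mouth_open")
  }
  out$kin <- fuse_or_handle(kinect, "kinect", kin_cols)
  fm <- dplyr::bind_cols(purrr::compact(out))
  structure(fm, class = c("feature_matrix", class(tibble())))
}

# per-segment motion features on the movement timeline; torso aggregates
# the three back IMUs by the arithmetic mean of their angles, and torso AL
# by the mean of the three back activity levels
wings_features <- function(wings, al_window_s = 1, strict_divisor = FALSE) {
  rate <- stream_rate(wings)
  w <- as_tibble(wings)
  complete <- stats::complete.cases(w)
  w <- w[complete, , drop = FALSE]
  if (!nrow(w)) abort_parameter("no complete motion rows")
  imu_feats <- purrr::map(rlang::set_names(WINGS_IMUS), function(id) {
    cols <- paste0(id, "_", c("acclx", "accly", "acclz", "magx", "magy", "magz"))
    s <- setNames(w[cols], c("acclx", "accly", "acclz", "magx", "magy", "magz"))
    o <- orientation_from_accel_mag(s)
    al <- rolling_activity_level(s$acclx, s$accly, s$acclz, rate,
      window_s = al_window_s, strict_divisor = strict_divisor
    )
    tibble(
      roll = o$roll * 180 / pi, pitch = o$pitch * 180 / pi,
      yaw = o$yaw * 180 / pi, al = al
    )
  })
  seg <- function(id) {
    setNames(imu_feats[[id]], paste0(id, "_", names(imu_feats[[id]])))
  }
  torso <- (imu_feats$bk1 + imu_feats$bk2 + imu_feats$bk3) / 3
  torso <- setNames(torso, paste0("torso_", names(torso)))
  bind_cols(
    tibble(timestamp_ms = w$timestamp_ms),
    seg("lfa"), seg("rfa"), seg("lua"), seg("rua"), torso
  )
}
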