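test_that("activity level is the mean acceleration magnitude", {
  expect_equal(activity_level(rep(0, 10), rep(0, 10), rep(1, 10)), 1)
  expect_equal(activity_level(0, 0, 0), 0)
  set.seed(9)
  ax <- rnorm(30)
  ay <- rnorm(30)
  az <- rnorm(30)
  expect_equal(
    activity_level(ax, ay, az),
    sum(sqrt(ax^2 + ay^2 + az^2)) / 30
  )
  # strict divisor variant only rescales
  expect_equal(
    activity_level(ax, ay, az, strict_divisor = TRUE),
    activity_level(ax, ay, az) * 30 / 7
  )
  expect_error(activity_level(numeric(0), numeric(0), numeric(0)),
    class = "escalert_parameter_error"
  )
})

test_that("heart rate recovers constructed pulse trains", {
  hr60 <- heart_rate_from_bvp(make_pulse_stream(seq(1, 59, by = 1), 60))
  expect_equal(
    unique(round(hr60$hr_bpm[!is.na(hr60$hr_bpm)], 6)), 60
  )
  hr90 <- heart_rate_from_bvp(make_pulse_stream(seq(1, 59, by = 1 / 1.5), 60))
  expect_equal(median(hr90$hr_bpm, na.rm = TRUE), 90, tolerance = 0.01)
  # alternating 0.8/1.0 s inter-beat intervals -> 60/0.9 bpm
  beats <- 1 + cumsum(rep(c(0.8, 1.0), 28))
  hr_alt <- heart_rate_from_bvp(make_pulse_stream(beats, 60))
  expect_equal(median(hr_alt$hr_bpm, na.rm = TRUE), 60 / 0.9, tolerance = 0.01)
  # fewer than two peaks in the window -> missing
  sparse <- make_pulse_stream(c(5), 20)
  expect_true(all(is.na(heart_rate_from_bvp(sparse)$hr_bpm)))
})

test_that("EDA decomposition is additive and separates tonic from phasic", {
  rate <- 4
  t <- seq(0, 300, by = 1 / rate)
  const <- make_stream(list(eda_us = rep(2, length(t))), rate, "eda")
  names(const)[2] <- "eda_us"
  d0 <- eda_decompose(const)
  expect_equal(d0$scl_us, rep(2, length(t)), tolerance = 1e-6)
  expect_lt(max(abs(d0$scr_us)), 1e-6)

  ramp <- make_stream(list(eda_us = 1 + 2 * t / 300), rate, "eda")
  dr <- eda_decompose(ramp)
  mid <- t > 60 & t < 240
  expect_lt(max(abs(dr$scl_us[mid] - ramp$eda_us[mid]) / ramp$eda_us[mid]), 0.05)
  # additivity holds everywhere, exactly
  expect_lt(max(abs(dr$scl_us + dr$scr_us - ramp$eda_us)), 1e-9)

  # a 4-s transient of 0.5 uS lands in the phasic component
  x <- 1 + 2 * t / 300
  ev <- t >= 150 & t < 154
  x[ev] <- x[ev] + 0.5 * sin(pi * (t[ev] - 150) / 4)
  burst <- make_stream(list(eda_us = x), rate, "eda")
  db <- eda_decompose(burst)
  expect_gt(max(db$scr_us[ev]), 0.25)

  neg <- make_stream(list(eda_us = c(rep(1, 50), -0.1, rep(1, 50))), rate, "eda")
  expect_error(eda_decompose(neg), class = "escalert_parameter_error")
})

test_that("fusion uses the timestamp-closest sample with earlier-tie rule", {
  wings_ts <- c(0, 500, 1000)
  feat <- tibble::tibble(timestamp_ms = c(875, 1125), v = c(10, 20))
  idx <- escalert:::nearest_index(wings_ts, feat$timestamp_ms)
  expect_equal(feat$v[idx], c(10, 10, 10)) # 1000 is 125 from both -> earlier
  feat2 <- tibble::tibble(timestamp_ms = c(850, 1100), v = c(10, 20))
  expect_equal(feat2$v[escalert:::nearest_index(wings_ts, feat2$timestamp_ms)],
    c(10, 10, 20))
})

test_that("the fused matrix sits on the movement timeline with 32 strict features", {
  subj <- generate_subject(scaled_profile(0.15), seed = 4)
  s <- subj$sessions[[2]] # a test session
  pp <- preprocess_session(s$streams)
  fm <- build_feature_matrix(pp$wings,
    hr = pp$hr, eda_feat = pp$eda_feat,
    e4_acc = pp$e4_acc, kinect = pp$kinect
  )
  expect_equal(length(setdiff(names(fm), "timestamp_ms")), 32L)
  expect_false(anyNA(fm))
  # basis rule: one row per (complete) movement-stream instant
  n_complete <- sum(stats::complete.cases(tibble::as_tibble(pp$wings)))
  expect_equal(nrow(fm), n_complete)
  # fused values appear verbatim in their source streams
  expect_true(all(fm$scl_us %in% pp$eda_feat$scl_us))
  expect_true(all(fm$hr_bpm %in% pp$hr$hr_bpm))
  expect_true(all(fm$face_happy %in% c(0, 0.5, 1)))
  # extended mode adds the two extra facial channels
  fm_ext <- build_feature_matrix(pp$wings,
    hr = pp$hr, eda_feat = pp$eda_feat,
    e4_acc = pp$e4_acc, kinect = pp$kinect, feature_set = "extended"
  )
  expect_equal(length(setdiff(names(fm_ext), "timestamp_ms")), 34L)
  # paper-strict: a missing modality is an error unless explicitly allowed
  expect_error(
    build_feature_matrix(pp$wings,
      hr = NULL, eda_feat = pp$eda_feat,
      e4_acc = pp$e4_acc, kinect = pp$kinect
    ),
    class = "escalert_parameter_error"
  )
  expect_warning(
    fm_drop <- build_feature_matrix(pp$wings,
      hr = NULL, eda_feat = pp$eda_feat,
      e4_acc = pp$e4_acc, kinect = pp$kinect, require_all = FALSE
    ),
    "absent"
  )
  expect_false("hr_bpm" %in% names(fm_drop))
})

test_that("feature extraction is deterministic given streams and configuration", {
  subj <- generate_subject(scaled_profile(0.1), seed = 21)
  s <- subj$sessions[[2]]
  f1 <- subject_features(subj)$fms[[2]]
  f2 <- subject_features(subj)$fms[[2]]
  expect_identical(f1, f2)
})
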