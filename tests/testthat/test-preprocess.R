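test_that("low-pass filter matches its analytic magnitude response", {
  rate <- 32
  t <- seq(0, 20, by = 1 / rate)
  mid <- t > 3 & t < 17 # away from edge transients

  dc <- make_stream(list(x = rep(1, length(t))), rate)
  expect_lt(max(abs(lowpass_filter(dc, 10)$x[mid] - 1)), 1e-6)

  for (f in c(1, 5, 14)) {
    s <- make_stream(list(x = sin(2 * pi * f * t)), rate)
    got <- max(abs(lowpass_filter(s, 10)$x[mid]))
    expect_equal(got, butter_filtfilt_gain(f, 10, rate), tolerance = 0.02)
  }
  # the endpoint behaviours the analysis relies on
  s1 <- make_stream(list(x = sin(2 * pi * 1 * t)), rate)
  expect_gt(max(abs(lowpass_filter(s1, 10)$x[mid])), 0.95)
  s14 <- make_stream(list(x = sin(2 * pi * 14 * t)), rate)
  expect_lt(max(abs(lowpass_filter(s14, 10)$x[mid])), 0.2)

  expect_error(lowpass_filter(s1, 16), class = "escalert_parameter_error")
  expect_error(lowpass_filter(s1, 20), class = "escalert_parameter_error")
})

test_that("band-pass filter rejects DC and drift but passes the mid-band", {
  rate <- 64
  t <- seq(0, 20, by = 1 / rate)
  mid <- t > 3 & t < 17

  dc <- make_stream(list(x = rep(2, length(t))), rate)
  expect_lt(max(abs(bandpass_filter(dc, 1, 8)$x[mid])), 1e-3)

  s4 <- make_stream(list(x = sin(2 * pi * 4 * t)), rate)
  expect_equal(max(abs(bandpass_filter(s4, 1, 8)$x[mid])), 1, tolerance = 0.1)

  drift <- make_stream(list(x = sin(2 * pi * 0.1 * t)), rate)
  expect_lt(max(abs(bandpass_filter(drift, 1, 8)$x[mid])), 0.1)

  expect_error(bandpass_filter(s4, 8, 1), class = "escalert_parameter_error")
  expect_error(bandpass_filter(s4, 0, 8), class = "escalert_parameter_error")
})

test_that("filters are linear operators", {
  rate <- 32
  t <- seq(0, 10, by = 1 / rate)
  set.seed(5)
  x <- rnorm(length(t))
  y <- sin(2 * pi * 3 * t)
  a <- 2.5
  b <- -1.2
  sx <- make_stream(list(v = x), rate)
  sy <- make_stream(list(v = y), rate)
  sxy <- make_stream(list(v = a * x + b * y), rate)
  for (f in list(
    function(s) lowpass_filter(s, 10),
    function(s) bandpass_filter(s, 1, 8)
  )) {
    expect_lt(max(abs(f(sxy)$v - (a * f(sx)$v + b * f(sy)$v))), 1e-9)
  }
})

test_that("numeric imputation equals the brute-force k-nearest-neighbour mean", {
  s <- make_stream(list(x = as.numeric(0:39)), rate = 10)
  gap <- c(11, 25)
  s$x[gap] <- NA
  out <- impute_numeric(s, k = 20)
  for (i in gap) {
    avail <- which(!is.na(s$x))
    d <- abs(s$timestamp_ms[avail] - s$timestamp_ms[i])
    nn <- avail[order(d, s$timestamp_ms[avail])][1:20]
    expect_equal(out$x[i], mean(s$x[nn]))
  }
  # non-missing values untouched; imputed values within neighbour range
  expect_equal(out$x[-gap], s$x[-gap])
  expect_true(all(out$x[gap] >= min(s$x, na.rm = TRUE) &
    out$x[gap] <= max(s$x, na.rm = TRUE)))

  # constant channel gap fills with the constant
  s2 <- make_stream(list(x = rep(5, 30)), rate = 10)
  s2$x[7] <- NA
  expect_equal(impute_numeric(s2, k = 20)$x[7], 5)

  # fewer than k available: all are used
  s3 <- make_stream(list(x = c(1, 2, NA, 4, 8, 16, 32, 64)), rate = 10)
  expect_equal(impute_numeric(s3, k = 20)$x[3], mean(c(1, 2, 4, 8, 16, 32, 64)))

  s4 <- make_stream(list(x = rep(NA_real_, 10)), rate = 10)
  expect_error(impute_numeric(s4), class = "escalert_parameter_error")
})

test_that("categorical imputation takes the k-nearest mode with nearest tie-break", {
  # gap surrounded entirely by 1.0
  s <- make_stream(list(x = rep(1, 30)), rate = 10)
  s$x[15] <- NA
  expect_equal(impute_categorical(s, k = 20)$x[15], 1)

  # twelve 0.5 and eight 0 among the 20 nearest -> 0.5
  x <- c(rep(0.5, 12), NA, rep(0, 8))
  s2 <- make_stream(list(x = x), rate = 10)
  expect_equal(impute_categorical(s2, k = 20)$x[13], 0.5)
  expect_true(all(impute_categorical(s2, k = 20)$x %in% c(0, 0.5, 1)))

  # 10 vs 10 tie: the single nearest sample's class wins
  x3 <- c(rep(0, 10), NA, rep(1, 10))
  s3 <- make_stream(list(x = x3), rate = 10)
  # nearest available to index 11 is index 10 (earlier on exact distance tie)
  expect_equal(impute_categorical(s3, k = 20)$x[11], 0)
})

test_that("corruption scrubbing counts and masks without dropping rows", {
  set.seed(3)
  s <- make_stream(list(acclx = rnorm(1000, 0, 0.1), magx = rnorm(1000)), rate = 15)
  clean <- scrub_corrupted(s)
  expect_equal(as.data.frame(clean$stream), as.data.frame(s))
  expect_equal(clean$report$fraction, c(0, 0))

  bad <- s
  bad$acclx[c(10, 500, 900)] <- c(Inf, 200, NaN) # 200 g exceeds full scale
  res <- scrub_corrupted(bad)
  expect_equal(res$report$fraction[res$report$channel == "acclx"], 3 / 1000)
  expect_true(all(is.na(res$stream$acclx[c(10, 500, 900)])))
  expect_equal(nrow(res$stream), 1000L)
  # magnetometer values are not range-limited, only finiteness-checked
  bad2 <- s
  bad2$magx[5] <- 200
  expect_equal(sum(scrub_corrupted(bad2)$report$n_corrupted), 0L)
})

test_that("simulated corruption rate is recovered within binomial error", {
  prof <- scaled_profile(0.3, corruption_rate = 0.003)
  subj <- generate_subject(prof, seed = 17)
  n_tot <- 0
  n_bad <- 0
  for (s in subj$sessions) {
    rep <- scrub_corrupted(s$streams$wings)$report
    n_tot <- n_tot + nrow(s$streams$wings)
    n_bad <- n_bad + sum(rep$n_corrupted)
  }
  p_hat <- n_bad / n_tot
  se <- sqrt(0.003 * 0.997 / n_tot)
  expect_lt(abs(p_hat - 0.003), 4 * se + 1e-4)
})

test_that("short gaps are bridged linearly and long gaps left missing", {
  s <- make_stream(list(x = as.numeric(1:20)), rate = 10)
  s$x[c(5, 6)] <- NA # short gap
  s$x[10:13] <- NA # long gap
  out <- bridge_gaps(s, max_gap = 2)
  expect_equal(out$x[5:6], c(5, 6))
  expect_true(all(is.na(out$x[10:13])))
})
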