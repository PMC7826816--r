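# shared in-code fixtures; everything is generated, nothing is stored

# minimal regular-rate stream with arbitrary channels
make_stream <- function(values, rate, modality = "test") {
  n <- length(values[[1]])
  ts <- floor((seq_len(n) - 1) * 1000 / rate)
  sensor_stream(
    tibble::tibble(timestamp_ms = ts, !!!values),
    modality, rate
  )
}

# gaussian-bump pulse train at given beat times (s)
make_pulse_stream <- function(beat_times_s, dur_s, rate = 64) {
  t <- seq(0, dur_s, by = 1 / rate)
  x <- numeric(length(t))
  for (tb in beat_times_s) x <- x + exp(-(t - tb)^2 / (2 * 0.025^2))
  sensor_stream(tibble::tibble(timestamp_ms = floor(t * 1000), bvp = x), "bvp", rate)
}

# a small well-formed test-session event log
make_test_log <- function(session_id = "s1") {
  event_log(
    tibble::tibble(
      timestamp_ms = c(0, 0, 5000, 95500, 95500, 110000, 111000, 115000, 200000),
      event_kind = c(
        "session_start", "SR_on", "calm_on", "EO_on", "calm_off",
        "precursor", "precursor", "SR_on", "session_end"
      )
    ),
    session_id = session_id, session_type = "test"
  )
}

# scaled-down default profile used throughout model-level tests: the same
# cycle structure as the full visit, shorter sessions
scaled_profile <- function(scale = 0.25, ...) {
  subject_profile(policy = protocol_policy(duration_scale = scale), ...)
}

# independent forward-kinematics oracle: explicit matrix composition along
# each root path, coded without the package's chain recursion
fk_oracle <- function(orientations, model) {
  o <- orientations[match(model$joint, orientations$joint), ]
  rot <- function(r, p, y) {
    Rx <- matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3)
    Ry <- matrix(c(cos(p), 0, -sin(p), 0, 1, 0, sin(p), 0, cos(p)), 3)
    Rz <- matrix(c(cos(y), sin(y), 0, -sin(y), cos(y), 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rx
  }
  path_to <- function(j) {
    path <- character()
    while (!is.na(j)) {
      path <- c(j, path)
      j <- model$parent[model$joint == j]
    }
    path
  }
  t(vapply(model$joint, function(j) {
    H <- diag(4)
    for (jj in path_to(j)) {
      i <- which(model$joint == jj)
      Hi <- rbind(
        cbind(rot(o$roll[i], o$pitch[i], o$yaw[i]), c(model$dx[i], model$dy[i], model$dz[i])),
        c(0, 0, 0, 1)
      )
      H <- H %*% Hi
    }
    H[1:3, 4]
  }, numeric(3)))
}

# random orientation set for a model, angles within the recoverable range
random_orientations <- function(model) {
  tibble::tibble(
    joint = model$joint,
    roll = runif(nrow(model), -1.4, 1.4),
    pitch = runif(nrow(model), -1.4, 1.4),
    yaw = runif(nrow(model), -3.1, 3.1)
  )
}

# analytic two-pass (zero-phase) magnitude response of a digital
# Butterworth filter designed by bilinear transform with prewarping
butter_filtfilt_gain <- function(f, fc, fs, order = 4) {
  warp <- function(x) tan(pi * x / fs)
  (1 / (1 + (warp(f) / warp(fc))^(2 * order)))
}
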