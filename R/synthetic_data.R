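# Seeded synthetic multimodal subjects.
#
# The generative model is invented (no clinical recordings are
# distributable): limb motion is sinusoid-plus-noise orientation traces
# rendered into accelerometer/magnetometer readings, blood volume pulse is
# a template-pulse train driven by an instantaneous heart rate, EDA is a
# slow tonic drift plus exponential-decay phasic transients, and facial
# scores are categorical draws with state-dependent probabilities.
# Defaults are tuned only to the published aggregate statistics: 26.9%
# face/head missingness, <0.3% IMU corruption, ~6:4 class ratio at the
# 90-s window, ~26 precursor episodes per ~54-min visit.
#
# Escalation intensity ramps from a jump of `escalation_floor` at onset
# (lead seconds before each precursor) to 1 at the precursor itself:
# graded escalation keeps 30/60/90-s labels separable while anything
# earlier than the lead is signal-free, which is what degrades a 120-s
# window.

#' Synthetic subject profile
#'
#' Describes one simulated child: baseline posture and motion, escalation
#' gains, physiological baselines, facial-score distributions,
#' missingness/corruption rates and the session behavior policy.
#'
#' @param subject_id subject label.
#' @param baseline_angles_deg named list of per-IMU `c(roll, pitch, yaw)`
#'   baselines in degrees (IMUs `lfa, rfa, lua, rua, bk1, bk2, bk3`);
#'   `NULL` for neutral defaults.
#' @param motion_amplitude_deg baseline angular excursion amplitude.
#' @param motion_freq_hz dominant limb-motion frequency.
#' @param motion_gain multiplier on motion amplitude and movement
#'   acceleration at full escalation (>= 1).
#' @param accel_activity_g baseline movement-acceleration scale (g).
#' @param accel_noise_g accelerometer sensor noise (g).
#' @param mag_noise magnetometer noise (field units).
#' @param dominant_side `"right"` or `"left"`; the dominant arm expresses
#'   the full motion gain, the other side 40% of the extra gain.
#' @param hr_baseline_bpm,hr_rise_bpm resting heart rate and its rise at
#'   full escalation.
#' @param scl_baseline_us tonic skin conductance level (microsiemens).
#' @param scr_rate_per_min baseline phasic-transient rate.
#' @param scr_rate_gain multiplier on the transient rate at full
#'   escalation.
#' @param scr_amp_us mean transient amplitude (microsiemens).
#' @param facial_calm,facial_escalated probabilities of score 1 for the
#'   happy / engaged / lookaway / eyes_closed / mouth_open channels in the
#'   two extreme states (interpolated by escalation intensity).
#' @param missingness_rate stationary Kinect dropout probability
#'   (default 0.269).
#' @param missing_run_samples mean length of a dropout burst (samples).
#' @param corruption_rate per-row IMU corruption probability
#'   (default 0.003).
#' @param escalation_lead_s escalation signature length before each
#'   precursor (default 90).
#' @param escalation_floor intensity jump at escalation onset, in (0, 1).
#' @param policy a [protocol_policy()].
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(subject_id = "S1",
                            baseline_angles_deg = NULL,
                            motion_amplitude_deg = 8,
                            motion_freq_hz = 0.7,
                            motion_gain = 2.5,
                            accel_activity_g = 0.12,
                            accel_noise_g = 0.03,
                            mag_noise = 0.02,
                            dominant_side = "right",
                            hr_baseline_bpm = 85,
                            hr_rise_bpm = 25,
                            scl_baseline_us = 2,
                            scr_rate_per_min = 2,
                            scr_rate_gain = 4,
                            scr_amp_us = 0.4,
                            facial_calm = c(
                              happy = 0.8, engaged = 0.85, lookaway = 0.1,
                              eyes_closed = 0.05, mouth_open = 0.1
                            ),
                            facial_escalated = c(
                              happy = 0.1, engaged = 0.2, lookaway = 0.6,
                              eyes_closed = 0.15, mouth_open = 0.4
                            ),
                            missingness_rate = 0.269,
                            missing_run_samples = 20,
                            corruption_rate = 0.003,
                            escalation_lead_s = 90,
                            escalation_floor = 0.35,
                            policy = protocol_policy()) {
  stopifnot(
    missingness_rate >= 0, missingness_rate < 1,
    corruption_rate >= 0, corruption_rate < 1,
    escalation_lead_s > 0, motion_gain >= 1, hr_rise_bpm >= 0,
    escalation_floor > 0, escalation_floor < 1
  )
  if (is.null(baseline_angles_deg)) {
    baseline_angles_deg <- list(
      lfa = c(10, -15, 5), rfa = c(-10, -15, -5),
      lua = c(5, -10, 8), rua = c(-5, -10, -8),
      bk1 = c(0, 5, 0), bk2 = c(0, 8, 0), bk3 = c(0, 11, 0)
    )
  }
  structure(as.list(environment()), class = "subject_profile")
}

# escalation intensity in [0, 1] at times t_s, given precursor times (s):
# 0 outside every pre-precursor window, else floor + (1 - floor) * progress
# of the closest covering window
escalation_intensity <- function(t_s, precursors_s, lead_s, floor_val) {
  e <- numeric(length(t_s))
  for (p in precursors_s) {
    in_w <- t_s >= p - lead_s & t_s <= p
    prog <- 1 - (p - t_s[in_w]) / lead_s
    e[in_w] <- pmax(e[in_w], floor_val + (1 - floor_val) * prog)
  }
  e
}

# bursty two-state missingness with given stationary rate and mean run
missing_mask <- function(n, rate, run) {
  if (rate <= 0) {
    return(logical(n))
  }
  q_exit <- 1 / run
  p_enter <- q_exit * rate / (1 - rate)
  state <- runif(1) < rate
  out <- logical(n)
  for (i in seq_len(n)) {
    out[i] <- state
    state <- if (state) runif(1) >= q_exit else runif(1) < p_enter
  }
  out
}

# render a true orientation trace into accelerometer + magnetometer
# readings (rows of R^T g and R^T m plus noise)
render_imu <- function(roll, pitch, yaw, move_g, noise_g, mag_noise,
                       g_ref = c(0, 0, 1), m_ref = c(0.5, 0, -0.4)) {
  n <- length(roll)
  sr <- sin(roll)
  cr <- cos(roll)
  sp <- sin(pitch)
  cp <- cos(pitch)
  sy <- sin(yaw)
  cy <- cos(yaw)
  # body-frame components of a world vector v: R^T v, rows of R
  body <- function(v) {
    cbind(
      cy * cp * v[1] + sy * cp * v[2] - sp * v[3],
      (cy * sp * sr - sy * cr) * v[1] + (sy * sp * sr + cy * cr) * v[2] + cp * sr * v[3],
      (sy * sr + cy * sp * cr) * v[1] + (sy * sp * cr - cy * sr) * v[2] + cp * cr * v[3]
    )
  }
  acc <- body(g_ref) + matrix(rnorm(3 * n, 0, noise_g), n) +
    matrix(rnorm(3 * n, 0, 1), n) * move_g
  mag <- body(m_ref) + matrix(rnorm(3 * n, 0, mag_noise), n)
  list(acc = acc, mag = mag)
}

simulate_wings <- function(dur_s, e_fun, p) {
  n <- floor(dur_s * 15) + 1L
  ts <- floor((seq_len(n) - 1) * 1000 / 15)
  t_s <- ts / 1000
  e <- e_fun(t_s)
  gain_extra <- p$motion_gain - 1
  side_gain <- function(imu) {
    dom <- (p$dominant_side == "right" && grepl("^r", imu)) ||
      (p$dominant_side == "left" && grepl("^l", imu))
    if (grepl("^bk", imu)) 0.8 else if (dom) 1 else 0.4
  }
  cols <- list(timestamp_ms = ts)
  for (imu in WINGS_IMUS) {
    base <- p$baseline_angles_deg[[imu]] * pi / 180
    amp <- (p$motion_amplitude_deg * pi / 180) *
      (1 + gain_extra * side_gain(imu) * e)
    ph <- runif(3, 0, 2 * pi)
    f <- p$motion_freq_hz * runif(1, 0.8, 1.2)
    roll <- base[1] + amp * sin(2 * pi * f * t_s + ph[1])
    pitch <- base[2] + 0.8 * amp * sin(2 * pi * f * 1.3 * t_s + ph[2])
    yaw <- base[3] + 0.6 * amp * sin(2 * pi * f * 0.7 * t_s + ph[3])
    move_g <- p$accel_activity_g * (1 + gain_extra * side_gain(imu) * e)
    r <- render_imu(roll, pitch, yaw, move_g, p$accel_noise_g, p$mag_noise)
    cols[[paste0(imu, "_acclx")]] <- r$acc[, 1]
    cols[[paste0(imu, "_accly")]] <- r$acc[, 2]
    cols[[paste0(imu, "_acclz")]] <- r$acc[, 3]
    cols[[paste0(imu, "_magx")]] <- r$mag[, 1]
    cols[[paste0(imu, "_magy")]] <- r$mag[, 2]
    cols[[paste0(imu, "_magz")]] <- r$mag[, 3]
  }
  df <- as_tibble(cols)
  # corrupt a small fraction of rows: one random sensor channel blows up
  bad_rows <- which(runif(n) < p$corruption_rate)
  chans <- setdiff(names(df), "timestamp_ms")
  for (i in bad_rows) {
    ch <- sample(chans, 1)
    df[[ch]][i] <- if (runif(1) < 0.5) Inf else {
      if (grepl("accl", ch)) 500 else NaN
    }
  }
  sensor_stream(df, "wings", 15)
}

simulate_bvp <- function(dur_s, e_fun, p) {
  rate <- 64
  n <- floor(dur_s * rate) + 1L
  t_s <- (seq_len(n) - 1) / rate
  hr <- p$hr_baseline_bpm + p$hr_rise_bpm * e_fun(t_s) +
    1.5 * sin(2 * pi * t_s / 47) # slow autonomic wander
  phase <- cumsum(hr / 60) / rate
  beats <- which(diff(floor(phase)) == 1L)
  x <- rnorm(n, 0, 0.02)
  half <- round(0.06 * rate) # gaussian systolic bump, sigma 60 ms / 2.5
  kern <- exp(-((-half:half) / (0.025 * rate))^2 / 2)
  for (b in beats) {
    idx <- (b - half):(b + half)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + kern[ok] * runif(1, 0.9, 1.1)
  }
  sensor_stream(
    tibble(timestamp_ms = floor(t_s * 1000), bvp = x),
    "bvp", rate
  )
}

simulate_eda <- function(dur_s, e_fun, p) {
  rate <- 4
  n <- floor(dur_s * rate) + 1L
  t_s <- (seq_len(n) - 1) / rate
  e <- e_fun(t_s)
  scl <- p$scl_baseline_us + 0.3 * sin(2 * pi * t_s / 600) + 0.4 * e
  rate_per_s <- p$scr_rate_per_min / 60 * (1 + p$scr_rate_gain * e)
  events <- which(runif(n) < rate_per_s / rate)
  x <- scl
  decay_len <- 8 * rate
  template <- exp(-(0:decay_len) / (2.5 * rate)) * (1 - exp(-(0:decay_len) / (0.6 * rate)))
  template <- template / max(template)
  for (ev in events) {
    idx <- ev:min(n, ev + decay_len)
    x[idx] <- x[idx] + template[seq_along(idx)] * p$scr_amp_us * runif(1, 0.6, 1.4)
  }
  x <- pmax(x + rnorm(n, 0, 0.01), 0.01)
  sensor_stream(
    tibble(timestamp_ms = floor(t_s * 1000), eda_us = x),
    "eda", rate
  )
}

simulate_e4_acc <- function(dur_s, e_fun, p) {
  rate <- 32
  n <- floor(dur_s * rate) + 1L
  t_s <- (seq_len(n) - 1) / rate
  e <- e_fun(t_s)
  scale <- p$accel_activity_g * (1 + (p$motion_gain - 1) * e)
  wob <- 2 * pi * p$motion_freq_hz * t_s
  sensor_stream(
    tibble(
      timestamp_ms = floor(t_s * 1000),
      ax = 0.15 * sin(wob) * (1 + e) + rnorm(n, 0, 1) * scale,
      ay = 0.15 * cos(wob * 0.8) * (1 + e) + rnorm(n, 0, 1) * scale,
      az = 1 + rnorm(n, 0, 1) * scale
    ),
    "e4_acc", rate
  )
}

simulate_kinect <- function(dur_s, e_fun, p) {
  rate <- 10
  n <- floor(dur_s * rate) + 1L
  t_s <- (seq_len(n) - 1) / rate
  e <- e_fun(t_s)
  amp <- 5 * (1 + (p$motion_gain - 1) * e)
  score_draw <- function(p1) {
    # P(score=1) = p1; remaining mass split 30/70 between 0.5 and 0
    u <- runif(n)
    ifelse(u < p1, 1, ifelse(u < p1 + 0.3 * (1 - p1), 0.5, 0))
  }
  face <- purrr::map(
    rlang::set_names(c("happy", "engaged", "lookaway", "eyes_closed", "mouth_open")),
    function(ch) {
      p1 <- p$facial_calm[[ch]] + (p$facial_escalated[[ch]] - p$facial_calm[[ch]]) * e
      score_draw(p1)
    }
  )
  df <- tibble(
    timestamp_ms = floor(t_s * 1000),
    head_roll = amp * sin(2 * pi * 0.4 * t_s) + 2 * e * 6 + rnorm(n, 0, 1),
    head_pitch = -5 + amp * sin(2 * pi * 0.3 * t_s + 1) - 8 * e + rnorm(n, 0, 1),
    head_yaw = amp * sin(2 * pi * 0.25 * t_s + 2) + rnorm(n, 0, 1),
    face_happy = face$happy, face_engaged = face$engaged,
    face_lookaway = face$lookaway, face_eyes_closed = face$eyes_closed,
    face_mouth_open = face$mouth_open
  )
  miss <- missing_mask(n, p$missingness_rate, p$missing_run_samples)
  df[miss, setdiff(names(df), "timestamp_ms")] <- NA_real_
  sensor_stream(df, "kinect", rate)
}

#' Generate one complete synthetic subject
#'
#' Runs the session protocol to get a valid event log per session, then
#' renders all five sensor streams session by session with the latent
#' escalation process driving motion amplitude, heart rate, phasic EDA
#' rate, head motion and facial scores. Kinect rows are missing at the
#' profile's rate; a small fraction of IMU rows are corrupted.
#'
#' @param profile a [subject_profile()].
#' @param seed integer seed; identical seeds give identical subjects.
#' @return a `synthetic_subject` list with `subject_id`, `profile`, and
#'   `sessions`: per session, `streams` (named list of
#'   [sensor_stream()]s), `log` (the [event_log()]), and `ground_truth`
#'   (precursor times, escalating intervals, condition/calm timeline).
#' @export
generate_subject <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  withr::with_seed(seed, {
    visit <- run_protocol(profile$policy,
      seed = sample.int(2^30, 1),
      visit_id = profile$subject_id
    )
    sessions <- purrr::imap(visit$logs, function(lg, i) {
      dur_s <- max(lg$timestamp_ms) / 1000
      prec_s <- visit$precursors[[i]] / 1000
      e_fun <- function(t_s) {
        escalation_intensity(
          t_s, prec_s, profile$escalation_lead_s,
          profile$escalation_floor
        )
      }
      esc <- if (length(prec_s)) {
        tibble(
          t_start_ms = pmax(0, (prec_s - profile$escalation_lead_s) * 1000),
          t_end_ms = prec_s * 1000
        )
      } else {
        tibble(t_start_ms = numeric(), t_end_ms = numeric())
      }
      list(
        streams = list(
          wings = simulate_wings(dur_s, e_fun, profile),
          bvp = simulate_bvp(dur_s, e_fun, profile),
          eda = simulate_eda(dur_s, e_fun, profile),
          e4_acc = simulate_e4_acc(dur_s, e_fun, profile),
          kinect = simulate_kinect(dur_s, e_fun, profile)
        ),
        log = lg,
        ground_truth = list(
          precursors_ms = visit$precursors[[i]],
          escalating_intervals = esc,
          timeline = visit$timelines[[i]],
          intensity = e_fun
        )
      )
    })
    structure(
      list(
        subject_id = profile$subject_id, profile = profile,
        sessions = sessions
      ),
      class = "synthetic_subject"
    )
  })
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject profiles are drawn around the base profile:
#' `heterogeneity = 0` repeats the base profile exactly (subjects then
#' differ only through their stream/protocol seeds); larger values spread
#' physiological baselines, posture baselines, motion gains, facial
#' distributions and dominant side — which is what separates
#' individualized from group (leave-one-subject-out) performance.
#'
#' @param n number of subjects (>= 1).
#' @param heterogeneity nonnegative spread multiplier (0 = identical
#'   profiles; 1 = a strongly heterogeneous cohort).
#' @param seed integer seed.
#' @param base_profile the population-mean [subject_profile()].
#' @return list of `synthetic_subject`s named by subject id.
#' @export
generate_cohort <- function(n, heterogeneity = 0, seed = 1L,
                            base_profile = subject_profile()) {
  if (!is.numeric(n) || n < 1) abort_parameter("n must be >= 1")
  h <- heterogeneity
  profiles <- withr::with_seed(seed, purrr::map(seq_len(n), function(i) {
    p <- base_profile
    p$subject_id <- sprintf("S%02d", i)
    if (h > 0) {
      p$hr_baseline_bpm <- p$hr_baseline_bpm + rnorm(1, 0, 15 * h)
      p$hr_rise_bpm <- max(5, p$hr_rise_bpm * exp(rnorm(1, 0, 0.3 * h)))
      p$scl_baseline_us <- max(0.5, p$scl_baseline_us + rnorm(1, 0, 1 * h))
      p$motion_amplitude_deg <- p$motion_amplitude_deg * exp(rnorm(1, 0, 0.35 * h))
      p$motion_gain <- 1 + (p$motion_gain - 1) * exp(rnorm(1, 0, 0.35 * h))
      p$accel_activity_g <- p$accel_activity_g * exp(rnorm(1, 0, 0.35 * h))
      p$dominant_side <- sample(c("right", "left"), 1, prob = c(0.8, 0.2))
      p$baseline_angles_deg <- purrr::map(
        p$baseline_angles_deg,
        function(b) b + rnorm(3, 0, 12 * h)
      )
      shift <- function(v) {
        rlang::set_names(pmin(0.95, pmax(0.02, v + rnorm(length(v), 0, 0.12 * h))), names(v))
      }
      p$facial_calm <- shift(p$facial_calm)
      p$facial_escalated <- shift(p$facial_escalated)
    }
    p
  }))
  subjects <- purrr::imap(profiles, function(p, i) {
    generate_subject(p, seed = (seed + 7919L * i) %% .Machine$integer.max)
  })
  rlang::set_names(subjects, purrr::map_chr(profiles, "subject_id"))
}

#' Write a synthetic subject to a session directory
#'
#' One TSV per modality per session, one event-log TSV per session, and a
#' YAML manifest — the same formats [read_stream()] and [read_event_log()]
#' consume, so simulated visits are drop-in replacements for recordings.
#'
#' @param subject a `synthetic_subject`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- purrr::imap(subject$sessions, function(s, i) {
    sid <- log_session_id(s$log)
    streams <- purrr::imap(s$streams, function(st, mod) {
      f <- file.path(dir, sprintf("%s_%s.tsv", sid, mod))
      write_stream(st, f)
      basename(f)
    })
    ef <- file.path(dir, sprintf("%s_events.tsv", sid))
    write_event_log(s$log, ef)
    tibble(
      session_id = sid, session_type = log_session_type(s$log),
      events_file = basename(ef), streams = list(streams)
    )
  }) |> list_rbind()
  write_session_manifest(sessions, file.path(dir, "manifest.yaml"),
    subject_id = subject$subject_id
  )
}
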