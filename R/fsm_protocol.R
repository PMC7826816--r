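# The session-protocol finite state machine.
#
# An IISCA-style visit is five sessions in C,T,C,T,T order (a multielement
# design): control sessions present only the reinforcing condition (S^R),
# test sessions alternate evocative (EO) and reinforcing conditions. The
# EO condition may only begin after at least 90 s of *continuous* observed
# calm within S^R; any precursor, problem behavior or calm_off resets the
# calm timer. After a precursor in EO the therapist returns to S^R and the
# same 90-s calm requirement gates the next EO.

CTCTT <- c("control", "test", "control", "test", "test")
CALM_THRESHOLD_MS <- 90000

#' Create a fresh protocol state
#'
#' @param session_type `"control"` or `"test"`.
#' @param session_index position of this session in the visit schedule.
#' @return a `protocol_state` list: `phase` (`INIT`, `SR`, `EO`, `SUMMARY`,
#'   `END`), `calm` flag, `calm_elapsed_ms` (continuous calm within S^R),
#'   `t_ms` current clock, `seen_condition` and `session_type`/`index`.
#' @export
protocol_state <- function(session_type = c("test", "control"), session_index = 1L) {
  session_type <- match.arg(session_type)
  structure(
    list(
      phase = "INIT", session_type = session_type,
      session_index = session_index, calm = FALSE,
      calm_elapsed_ms = 0, t_ms = 0, seen_condition = FALSE
    ),
    class = "protocol_state"
  )
}

#' Is the state ready for an EO presentation?
#'
#' True only in S^R of a test session with at least 90 s of continuous calm.
#'
#' @param state a [protocol_state()].
#' @export
eo_ready <- function(state) {
  state$phase == "SR" && state$session_type == "test" &&
    state$calm && state$calm_elapsed_ms >= CALM_THRESHOLD_MS
}

# advance the clock; continuous calm accrues only while calm within S^R
advance_clock <- function(state, t_ms) {
  if (t_ms < state$t_ms) {
    abort_validation(sprintf("clock moved backwards: %d -> %d", state$t_ms, t_ms))
  }
  if (state$calm && state$phase == "SR") {
    state$calm_elapsed_ms <- state$calm_elapsed_ms + (t_ms - state$t_ms)
  }
  state$t_ms <- t_ms
  state
}

#' Advance the protocol clock without an event
#'
#' @param state a [protocol_state()].
#' @param dt_s elapsed seconds.
#' @return the updated state.
#' @export
fsm_tick <- function(state, dt_s) {
  advance_clock(state, state$t_ms + round(dt_s * 1000))
}

#' Apply one logged event to the protocol state
#'
#' Deterministic transition; illegal events raise an
#' `escalert_protocol_error` naming the event and timestamp. See
#' [replay_event_log()] to collect violations instead of stopping at the
#' first one.
#'
#' @param state a [protocol_state()].
#' @param event_kind one of the event-log kinds.
#' @param t_ms event timestamp (ms, session clock).
#' @return the updated state.
#' @export
fsm_step <- function(state, event_kind, t_ms = state$t_ms) {
  violation <- function(msg) {
    rlang::abort(sprintf("t=%d %s: %s", t_ms, event_kind, msg),
      class = c("escalert_protocol_error", "escalert_validation_error")
    )
  }
  if (state$phase == "END") violation("event after END")
  if (state$phase == "SUMMARY" && event_kind != "session_start") {
    violation("event after session_end")
  }
  state <- advance_clock(state, t_ms)
  switch(event_kind,
    session_start = {
      if (state$phase != "INIT") violation("session already started")
      state$phase <- "SR"
    },
    SR_on = {
      if (state$phase == "SR" && !state$seen_condition) {
        state$seen_condition <- TRUE # initial condition marker
      } else if (state$phase == "EO") {
        state$phase <- "SR"
        state$calm_elapsed_ms <- 0
      } else {
        violation("SR_on while not in EO")
      }
    },
    EO_on = {
      if (state$session_type == "control") {
        violation("EO in a control session (control sessions are S^R only)")
      }
      if (state$phase != "SR") violation("EO_on while not in S^R")
      if (!eo_ready(state)) {
        violation(sprintf(
          "EO without 90 s continuous calm (calm=%s, %.1f s accrued)",
          state$calm, state$calm_elapsed_ms / 1000
        ))
      }
      state$phase <- "EO"
      state$seen_condition <- TRUE
      state$calm_elapsed_ms <- 0
    },
    calm_on = {
      if (!state$phase %in% c("SR", "EO")) violation("calm_on outside a session")
      if (state$calm) violation("calm_on while already calm")
      state$calm <- TRUE
      state$calm_elapsed_ms <- 0
    },
    calm_off = {
      if (!state$calm) violation("calm_off while not calm")
      state$calm <- FALSE
      state$calm_elapsed_ms <- 0
    },
    precursor = ,
    problem_behavior = {
      if (!state$phase %in% c("SR", "EO")) violation("behavior event outside a session")
      state$calm_elapsed_ms <- 0
    },
    session_end = {
      if (!state$phase %in% c("SR", "EO")) violation("session_end outside a session")
      state$phase <- if (state$session_index >= length(CTCTT)) "END" else "SUMMARY"
    },
    violation("unknown event kind")
  )
  state
}

#' Replay an event log through the state machine
#'
#' Applies every entry through [fsm_step()], collecting protocol
#' violations rather than stopping, and reconstructs the latent
#' condition/calm timeline.
#'
#' @param log an [event_log()].
#' @param session_index position in the visit schedule (affects only the
#'   final phase).
#' @return a list: `violations` (tibble `timestamp_ms`, `event_kind`,
#'   `message`; zero rows for a protocol-valid log), `timeline` (tibble of
#'   segments `t_start_ms`, `t_end_ms`, `condition`, `calm`) and the final
#'   `state`.
#' @export
replay_event_log <- function(log, session_index = 1L) {
  state <- protocol_state(log_session_type(log), session_index)
  viol <- list()
  segs <- list()
  seg_start <- 0
  last_cond <- NA_character_
  last_calm <- FALSE
  note_segment <- function(t) {
    cond <- if (state$phase %in% c("SR", "EO")) state$phase else NA_character_
    if (!identical(cond, last_cond) || !identical(state$calm, last_calm)) {
      if (!is.na(last_cond) && t > seg_start) {
        segs[[length(segs) + 1L]] <<- tibble(
          t_start_ms = seg_start, t_end_ms = t,
          condition = last_cond, calm = last_calm
        )
      }
      seg_start <<- t
      last_cond <<- cond
      last_calm <<- state$calm
    }
  }
  for (i in seq_len(nrow(log))) {
    t <- log$timestamp_ms[i]
    kind <- log$event_kind[i]
    res <- tryCatch(
      {
        state <- fsm_step(state, kind, t)
        NULL
      },
      escalert_protocol_error = function(e) conditionMessage(e),
      escalert_validation_error = function(e) conditionMessage(e)
    )
    if (!is.null(res)) {
      viol[[length(viol) + 1L]] <- tibble(
        timestamp_ms = t, event_kind = kind, message = res
      )
    }
    note_segment(t)
  }
  list(
    violations = if (length(viol)) list_rbind(viol) else
      tibble(timestamp_ms = numeric(), event_kind = character(), message = character()),
    timeline = if (length(segs)) list_rbind(segs) else tibble(),
    state = state
  )
}

#' Default stochastic behavior policy for simulated sessions
#'
#' Latencies and event counts that drive [run_protocol()]. The defaults
#' emulate the published feasibility aggregates: per-session durations of
#' roughly 12.1/11.4/10/10.7/10.1 minutes, about 26 precursor episodes per
#' visit clustered into EO-triggered escalation cycles, and a ~6:4
#' calm/pre-precursor class ratio at the 90-s labeling window.
#'
#' @param session_minutes per-session durations for the five CTCTT
#'   sessions, minutes.
#' @param duration_scale multiplies all session durations (smaller values
#'   give proportionally shorter visits with the same cycle structure).
#' @param calm_latency_mean_s mean latency from the last escalated event to
#'   observed calm (gamma, shape 4).
#' @param eo_prec_latency_mean_s mean latency from EO onset to the first
#'   precursor (exponential, floored at 3 s).
#' @param eo_extra_prec_lambda Poisson mean of additional precursors in the
#'   same EO presentation (spaced exponentially, mean `eo_prec_gap_s`).
#' @param eo_prec_gap_s mean gap between within-EO precursors, seconds.
#' @param sr_return_delay_s therapist latency from the last EO precursor to
#'   re-imposing S^R.
#' @param sr_prec_lambda Poisson mean of de-escalation precursors after the
#'   return to S^R (spaced exponentially, mean `sr_prec_gap_s`).
#' @param sr_prec_gap_s mean gap between de-escalation precursors, seconds.
#' @param eo_reaction_s observer delay between calm readiness and EO onset.
#' @param control_prec_lambda Poisson mean of (rare) precursors in a
#'   control session.
#' @return a `protocol_policy` list.
#' @export
protocol_policy <- function(session_minutes = c(12.05, 11.37, 10.02, 10.71, 10.05),
                            duration_scale = 1,
                            calm_latency_mean_s = 25,
                            eo_prec_latency_mean_s = 15,
                            eo_extra_prec_lambda = 0.5,
                            eo_prec_gap_s = 8,
                            sr_return_delay_s = 4,
                            sr_prec_lambda = 0.9,
                            sr_prec_gap_s = 12,
                            eo_reaction_s = 2,
                            control_prec_lambda = 0.3) {
  structure(
    list(
      session_minutes = session_minutes * duration_scale,
      calm_latency_mean_s = calm_latency_mean_s,
      eo_prec_latency_mean_s = eo_prec_latency_mean_s,
      eo_extra_prec_lambda = eo_extra_prec_lambda,
      eo_prec_gap_s = eo_prec_gap_s,
      sr_return_delay_s = sr_return_delay_s,
      sr_prec_lambda = sr_prec_lambda,
      sr_prec_gap_s = sr_prec_gap_s,
      eo_reaction_s = eo_reaction_s,
      control_prec_lambda = control_prec_lambda
    ),
    class = "protocol_policy"
  )
}

rgamma_mean <- function(n, mean, shape = 4) rgamma(n, shape = shape, rate = shape / mean)

# one simulated session's event list, using the ambient RNG
simulate_session_events <- function(type, dur_s, policy) {
  ev <- list(c(0, "session_start"), c(0, "SR_on"))
  push <- function(t, kind) ev[[length(ev) + 1L]] <<- c(round(t * 1000), kind)
  t <- rgamma_mean(1, policy$calm_latency_mean_s)
  calm <- FALSE
  if (type == "control") {
    n_prec <- rpois(1, policy$control_prec_lambda)
    prec_t <- sort(runif(n_prec, 0.05, 0.9)) * dur_s
    if (t < dur_s) {
      push(t, "calm_on")
      calm <- TRUE
    }
    for (tp in prec_t) {
      if (tp <= t) next # only once settled
      push(tp, "precursor")
    }
  } else {
    if (t >= dur_s) t <- dur_s * 0.2 # degenerate short session: settle early
    push(t, "calm_on")
    calm <- TRUE
    calm_start <- t
    repeat {
      eo_t <- calm_start + 90 + rexp(1, 1 / policy$eo_reaction_s)
      # require room for at least the first precursor before session end
      if (eo_t + policy$eo_prec_latency_mean_s + 10 > dur_s) break
      push(eo_t, "EO_on")
      p1 <- eo_t + max(3, rexp(1, 1 / policy$eo_prec_latency_mean_s))
      if (p1 > dur_s - 5) p1 <- dur_s - 5
      push(p1, "precursor")
      push(p1, "calm_off")
      calm <- FALSE
      last <- p1
      for (i in seq_len(rpois(1, policy$eo_extra_prec_lambda))) {
        g <- last + rexp(1, 1 / policy$eo_prec_gap_s)
        if (g > dur_s - 5) break
        push(g, "precursor")
        last <- g
      }
      sr_t <- min(last + policy$sr_return_delay_s, dur_s - 2)
      push(sr_t, "SR_on")
      last <- sr_t
      for (i in seq_len(rpois(1, policy$sr_prec_lambda))) {
        g <- last + rexp(1, 1 / policy$sr_prec_gap_s)
        if (g > dur_s - 5) break
        push(g, "precursor")
        last <- g
      }
      calm_start <- last + rgamma_mean(1, policy$calm_latency_mean_s)
      if (calm_start + 95 > dur_s) break
      push(calm_start, "calm_on")
      calm <- TRUE
    }
  }
  push(dur_s, "session_end")
  m <- do.call(rbind, ev)
  tibble(
    timestamp_ms = as.numeric(m[, 1]),
    event_kind = m[, 2]
  ) |> arrange(.data$timestamp_ms, match(.data$event_kind, EVENT_KINDS))
}

#' Simulate a protocol-valid visit
#'
#' Generates the event logs of a full visit (default CTCTT) under a
#' stochastic behavior policy, together with the latent condition/calm
#' timeline recovered by replaying each log through the state machine.
#' Every generated log replays with zero violations.
#'
#' @param policy a [protocol_policy()].
#' @param schedule session types in order (default CTCTT).
#' @param seed integer seed.
#' @param visit_id label used to build session ids.
#' @return a `protocol_visit` list: `logs` (list of [event_log()]s),
#'   `timelines` (per-session segment tibbles), `precursors` (per-session
#'   precursor timestamp vectors) and `schedule`.
#' @export
run_protocol <- function(policy = protocol_policy(), schedule = CTCTT,
                         seed = 1L, visit_id = "visit1") {
  if (length(policy$session_minutes) < length(schedule)) {
    abort_parameter("policy needs one session duration per scheduled session")
  }
  logs <- withr::with_seed(seed, purrr::imap(schedule, function(type, i) {
    entries <- simulate_session_events(type, policy$session_minutes[i] * 60, policy)
    event_log(entries,
      session_id = sprintf("%s_s%d_%s", visit_id, i, type),
      session_type = type
    )
  }))
  replays <- purrr::imap(logs, function(lg, i) replay_event_log(lg, i))
  bad <- purrr::keep(replays, function(r) nrow(r$violations) > 0)
  if (length(bad)) {
    abort_validation(sprintf(
      "behavior policy produced an illegal event sequence: %s",
      bad[[1]]$violations$message[1]
    ))
  }
  structure(
    list(
      logs = logs,
      timelines = purrr::map(replays, "timeline"),
      precursors = purrr::map(logs, function(lg) {
        lg$timestamp_ms[lg$event_kind == "precursor"]
      }),
      schedule = schedule
    ),
    class = "protocol_visit"
  )
}
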