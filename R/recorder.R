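# Discrete-event simulation of the lander's recording protocol: a magnet on
# a reed switch drives the recorder through its states while the housing
# steps through Maltese-cross-indexed rotations.

recorder_states <- c("STARTING", "READY", "WORKING", "STANDBY", "SHUTDOWN")
recorder_events <- c("boot_complete", "magnet", "timer_tick", "shutdown_magnet")

#' Rotation protocol configuration
#'
#' The standard observation protocol: the housing rotates `step_deg` every
#' `dwell_s` seconds, so `frames_per_rotation` contiguous fixed frames cover
#' a full 360 deg rotation (~3 min with the defaults), and one observation
#' is `rotations_per_observation` undisturbed rotations (~9 min).
#'
#' @param step_deg Rotation step, degrees (default 60).
#' @param dwell_s Seconds per fixed frame (default 30).
#' @param frames_per_rotation Frames per full rotation (default 6);
#'   `step_deg * frames_per_rotation` must equal 360.
#' @param rotations_per_observation Rotations per observation (default 3).
#' @param sensor_sample_period_s Seconds between metadata samples
#'   (default 10).
#' @param motor_align_s Motor alignment delay on entering WORKING, seconds
#'   (default 0; its real duration is small and unspecified).
#' @param start_time POSIXct wall-clock time of t = 0 for timestamping the
#'   metadata log (UTC).
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(step_deg = 60, dwell_s = 30,
                            frames_per_rotation = 6,
                            rotations_per_observation = 3,
                            sensor_sample_period_s = 10,
                            motor_align_s = 0,
                            start_time = as.POSIXct("2021-10-01 08:00:00",
                                                    tz = "UTC")) {
  stopifnot(
    step_deg > 0, dwell_s > 0, frames_per_rotation > 0,
    rotations_per_observation > 0, sensor_sample_period_s > 0,
    motor_align_s >= 0
  )
  if (!isTRUE(all.equal(step_deg * frames_per_rotation, 360))) {
    stop("step_deg * frames_per_rotation must equal 360", call. = FALSE)
  }
  structure(
    list(
      step_deg = step_deg, dwell_s = dwell_s,
      frames_per_rotation = as.integer(frames_per_rotation),
      rotations_per_observation = as.integer(rotations_per_observation),
      sensor_sample_period_s = sensor_sample_period_s,
      motor_align_s = motor_align_s, start_time = start_time
    ),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(
    "<protocol_config> %g deg every %g s (%d frames/rotation), %d rotations/observation\n",
    x$step_deg, x$dwell_s, x$frames_per_rotation, x$rotations_per_observation
  ))
  invisible(x)
}

#' Recorder state transition
#'
#' The recorder's life cycle: it boots (STARTING), signals readiness
#' (READY, LED still), starts rotating and recording on a magnet swipe
#' (WORKING), is set to standby by another swipe (STANDBY, recording and
#' motor stopped), can resume (STANDBY -> WORKING on magnet), and shuts
#' down from standby on the shutdown swipe, at which point the metadata CSV
#' is flushed. `timer_tick` (a dwell period elapsing) is only legal while
#' WORKING, where it advances the rotation. Any other state/event pair is a
#' protocol error.
#'
#' @param state One of `"STARTING"`, `"READY"`, `"WORKING"`, `"STANDBY"`,
#'   `"SHUTDOWN"`.
#' @param event One of `"boot_complete"`, `"magnet"`, `"timer_tick"`,
#'   `"shutdown_magnet"`.
#' @return The next state (character scalar).
#' @examples
#' recorder_transition("READY", "magnet")  # "WORKING"
#' @export
recorder_transition <- function(state, event) {
  state <- match.arg(state, recorder_states)
  event <- match.arg(event, recorder_events)
  nxt <- switch(state,
    STARTING = if (event == "boot_complete") "READY",
    READY = if (event == "magnet") "WORKING",
    WORKING = switch(event, magnet = "STANDBY", timer_tick = "WORKING", NULL),
    STANDBY = switch(event, magnet = "WORKING", shutdown_magnet = "SHUTDOWN",
                     NULL),
    SHUTDOWN = NULL
  )
  if (is.null(nxt)) {
    stop(sprintf("protocol error: event '%s' is illegal in state %s",
                 event, state), call. = FALSE)
  }
  nxt
}

#' Rotation index from the Maltese-cross step count
#'
#' The Maltese cross makes every motor engagement an exact `step_deg`
#' rotation, so the housing orientation is fully determined by the step
#' count.
#'
#' @param step_count Number of completed steps (>= 0).
#' @param config A [protocol_config()].
#' @return List with `position` (frame index, `0 .. frames_per_rotation-1`)
#'   and `cumulative_angle_deg`.
#' @examples
#' rotation_index(7)  # position 1, 420 degrees
#' @export
rotation_index <- function(step_count, config = protocol_config()) {
  stopifnot(all(step_count >= 0), inherits(config, "protocol_config"))
  list(
    position = step_count %% config$frames_per_rotation,
    cumulative_angle_deg = step_count * config$step_deg
  )
}

#' Sensor sources for the recorder simulator
#'
#' Pluggable pressure/temperature sources: each returns a function of a
#' vector of simulation times (s) producing a data frame with
#' `pressure_dbar` and `temperature_C`.
#'
#' @param pressure_dbar,temperature_C Constant values (defaults: 10 m depth,
#'   temperate coastal water).
#' @param pressure_rate,temperature_rate Linear drift per second
#'   (`sensor_ramp`).
#' @param seed RNG seed (`sensor_random`).
#' @param pressure_sd,temperature_sd Gaussian jitter sd (`sensor_random`).
#' @return A function `f(times_s)` returning a data frame.
#' @export
sensor_constant <- function(pressure_dbar = 10.1, temperature_C = 18.5) {
  function(t) data.frame(pressure_dbar = rep(pressure_dbar, length(t)),
                         temperature_C = rep(temperature_C, length(t)))
}

#' @rdname sensor_constant
#' @export
sensor_ramp <- function(pressure_dbar = 10.1, temperature_C = 18.5,
                        pressure_rate = 0, temperature_rate = -0.001) {
  function(t) data.frame(pressure_dbar = pressure_dbar + pressure_rate * t,
                         temperature_C = temperature_C + temperature_rate * t)
}

#' @rdname sensor_constant
#' @export
sensor_random <- function(seed, pressure_dbar = 10.1, temperature_C = 18.5,
                          pressure_sd = 0.02, temperature_sd = 0.05) {
  function(t) with_seed(seed, data.frame(
    pressure_dbar = pressure_dbar + stats::rnorm(length(t), 0, pressure_sd),
    temperature_C = temperature_C + stats::rnorm(length(t), 0, temperature_sd)
  ))
}

#' Simulate a recording observation
#'
#' Runs the recorder through one full session: boot, ready, start on magnet,
#' `n_rotations` complete rotations (each `frames_per_rotation` dwell
#' periods), standby on magnet, shutdown on the shutdown swipe. Video is one
#' contiguous segment covering the WORKING phase; metadata (pressure,
#' temperature) is sampled every `sensor_sample_period_s` from the start of
#' recording to its end, inclusive.
#'
#' @param config A [protocol_config()].
#' @param n_rotations Number of complete rotations (default: the config's
#'   `rotations_per_observation`); 0 gives an empty recording.
#' @param sensor_source A sensor function (see [sensor_constant()]).
#' @return An object of class `session_log`: `events` (data frame
#'   `sim_time_s, state, event, cumulative_angle_deg`), `metadata` (data
#'   frame `time_s, timestamp_iso, pressure_dbar, temperature_C`),
#'   `video_segments` (`start_s, end_s`), `config`, and `duration_s` of the
#'   WORKING phase.
#' @examples
#' log <- run_observation()
#' log$duration_s  # 540 s for three rotations
#' @export
run_observation <- function(config = protocol_config(),
                            n_rotations = config$rotations_per_observation,
                            sensor_source = sensor_constant()) {
  stopifnot(inherits(config, "protocol_config"), n_rotations >= 0)
  n_steps <- n_rotations * config$frames_per_rotation
  duration <- n_steps * config$dwell_s

  state <- "STARTING"
  t <- 0
  ev <- list()
  add <- function(time, event) {
    state <<- recorder_transition(state, event)
    steps <- length(Filter(function(e) e$event == "timer_tick", ev)) +
      (event == "timer_tick")
    ev[[length(ev) + 1]] <<- list(
      sim_time_s = time, state = state, event = event,
      cumulative_angle_deg = steps * config$step_deg
    )
  }
  add(t, "boot_complete")
  add(t, "magnet") # operator engages recording
  t <- t + config$motor_align_s
  for (s in seq_len(n_steps)) {
    t <- t + config$dwell_s
    add(t, "timer_tick") # dwell elapsed, Maltese cross advances one step
  }
  add(t, "magnet") # operator stops: standby
  add(t, "shutdown_magnet")
  events <- do.call(rbind, lapply(ev, as.data.frame))

  rec_start <- config$motor_align_s
  rec_end <- rec_start + duration
  if (duration > 0) {
    times <- seq(rec_start, rec_end, by = config$sensor_sample_period_s)
    sens <- sensor_source(times)
    metadata <- data.frame(
      time_s = times,
      timestamp_iso = format(config$start_time + times,
                             "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      pressure_dbar = sens$pressure_dbar,
      temperature_C = sens$temperature_C
    )
    segments <- data.frame(start_s = rec_start, end_s = rec_end)
  } else {
    metadata <- data.frame(time_s = numeric(0), timestamp_iso = character(0),
                           pressure_dbar = numeric(0),
                           temperature_C = numeric(0))
    segments <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }

  log <- structure(
    list(events = events, metadata = metadata, video_segments = segments,
         config = config, duration_s = duration),
    class = "session_log"
  )
  validate_session_log(log)
  log
}

#' Validate a session log's invariants
#'
#' Checks that event times are non-decreasing, the cumulative angle
#' increases in exact multiples of the rotation step, and the state sequence
#' follows the legal transition graph.
#'
#' @param log A `session_log`.
#' @return `log`, invisibly; errors on violation.
#' @export
validate_session_log <- function(log) {
  stopifnot(inherits(log, "session_log"))
  e <- log$events
  if (nrow(e)) {
    if (is.unsorted(e$sim_time_s)) stop("event times must be non-decreasing")
    ang <- diff(c(0, e$cumulative_angle_deg))
    if (any(ang < 0) || any(abs(ang %% log$config$step_deg) > 1e-9)) {
      stop("cumulative angle must increase in multiples of the step")
    }
    state <- "STARTING"
    for (i in seq_len(nrow(e))) {
      state <- recorder_transition(state, e$event[i]) # errors if illegal
      if (state != e$state[i]) stop("logged state differs from the FSM")
    }
  }
  if (nrow(log$metadata) && is.unsorted(log$metadata$time_s)) {
    stop("metadata times must be non-decreasing")
  }
  invisible(log)
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> WORKING %g s (%g rotations), %d events, %d metadata rows\n",
    x$duration_s, x$duration_s / (x$config$frames_per_rotation * x$config$dwell_s),
    nrow(x$events), nrow(x$metadata)
  ))
  invisible(x)
}

#' Write / read the session metadata CSV
#'
#' The metadata file the recorder flushes at shutdown: one row per sensor
#' sample with columns `timestamp_iso`, `pressure_dbar`, `temperature_C`
#' (ISO-8601 UTC timestamps, pressure in dbar, temperature in deg C).
#'
#' @param log A `session_log`.
#' @param path Output file path.
#' @return `write_session_csv` returns `path` invisibly; `read_session_csv`
#'   returns the metadata data frame.
#' @export
write_session_csv <- function(log, path) {
  validate_session_log(log)
  df <- log$metadata[, c("timestamp_iso", "pressure_dbar", "temperature_C")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  utils::read.csv(path, colClasses = c("character", "numeric", "numeric"))
}
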