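#' Define an automated pressure-step protocol
#'
#' Steps intraluminal pressure between \code{start} and \code{stop} in
#' increments of \code{step} mmHg, holding each level for \code{hold}
#' seconds, optionally superimposing a sinusoidal oscillation on the
#' setpoint to mimic pulsatile pressure in vivo (rates up to ~400
#' oscillations per minute, the murine heart rate).
#'
#' @param start,stop First and last pressure levels, mmHg (either
#'   direction).
#' @param step Level increment magnitude, mmHg; positive.
#' @param hold Seconds per level; positive. Default 120 s, a typical
#'   myogenic equilibration time.
#' @param oscillation Optional list \code{(amplitude, rate)}: amplitude in
#'   mmHg, rate in oscillations per minute (\code{<= 400}).
#' @return An object of class \code{pressure_protocol}.
#' @export
pressure_protocol <- function(start, stop, step, hold = 120,
                              oscillation = NULL) {
  if (!is.numeric(step) || step <= 0) stop("`step` must be positive")
  if (!is.numeric(hold) || hold <= 0) stop("`hold` must be positive")
  stopifnot(start >= 0, stop >= 0)
  if (!is.null(oscillation)) {
    stopifnot(is.list(oscillation), oscillation$amplitude >= 0,
              oscillation$rate > 0)
    if (oscillation$rate > 400) {
      stop("oscillation rate must be <= 400 per minute")
    }
  }
  structure(list(start = start, stop = stop, step = step, hold = hold,
                 oscillation = oscillation),
            class = "pressure_protocol")
}

#' Expand a protocol into its ordered pressure levels
#'
#' Levels run from \code{start} toward \code{stop} in increments of
#' \code{step} (direction inferred from the sign of \code{stop - start});
#' \code{stop} is always included, with the final step flagged
#' \code{partial} when \code{step} does not divide the span.
#'
#' @param start,stop,step,hold As in [pressure_protocol()]; alternatively
#'   pass a \code{pressure_protocol} as \code{start}.
#' @return A data.frame with columns \code{level}, \code{pressure_mmHg},
#'   \code{hold_s}, \code{partial}.
#' @examples
#' build_step_protocol(20, 100, 20, 120)$pressure_mmHg  # 20 40 60 80 100
#' @export
build_step_protocol <- function(start, stop = NULL, step = NULL,
                                hold = 120) {
  if (inherits(start, "pressure_protocol")) {
    p <- start
    start <- p$start; stop <- p$stop; step <- p$step; hold <- p$hold
  } else {
    p <- pressure_protocol(start, stop, step, hold)  # validates
  }
  if (start == stop) {
    levels <- start
  } else {
    dir <- sign(stop - start)
    levels <- seq(start, stop, by = dir * step)
    if (levels[length(levels)] != stop) levels <- c(levels, stop)
  }
  n <- length(levels)
  partial <- rep(FALSE, n)
  if (n >= 2L && abs(levels[n] - levels[n - 1L]) < step) partial[n] <- TRUE
  data.frame(level = seq_len(n), pressure_mmHg = levels,
             hold_s = hold, partial = partial)
}

#' A simulated pressure servo
#'
#' Behavioural stand-in for a myograph pressure controller: the delivered
#' pressure approaches the commanded setpoint as a first-order system with
#' the given time constant, and the reported (sensor) pressure optionally
#' carries Gaussian measurement noise.
#'
#' @param current_pressure Initial pressure, mmHg (>= 0).
#' @param time_constant First-order time constant, s; positive. Default 2.
#' @param sensor_noise_sd Sensor noise SD, mmHg (>= 0).
#' @return An object of class \code{simulated_servo}.
#' @export
simulated_servo <- function(current_pressure = 0, time_constant = 2,
                            sensor_noise_sd = 0) {
  stopifnot(current_pressure >= 0, sensor_noise_sd >= 0)
  if (time_constant <= 0) stop("`time_constant` must be positive")
  structure(list(current_pressure = current_pressure,
                 time_constant = time_constant,
                 sensor_noise_sd = sensor_noise_sd),
            class = "simulated_servo")
}

#' Simulate the servo pressure trace of a protocol
#'
#' Discrete-time loop at interval \code{dt}: at each step the true pressure
#' relaxes exactly one first-order step toward the current setpoint (level
#' plus oscillation term when configured); the sensor reading adds seeded
#' Gaussian noise. Level transitions occur at exact multiples of \code{dt}.
#'
#' @param protocol A [pressure_protocol()].
#' @param servo A [simulated_servo()].
#' @param dt Time step, s.
#' @param seed Seed for sensor noise.
#' @return A data.frame with columns \code{time_s}, \code{level},
#'   \code{setpoint_mmHg}, \code{pressure_mmHg} (true),
#'   \code{sensor_mmHg}, and an attribute \code{events}: a data.frame
#'   \code{(time_s, label, pressure_mmHg)} with one "pressure set" row per
#'   level transition.
#' @export
simulate_servo_trace <- function(protocol, servo, dt, seed = 1L) {
  stopifnot(inherits(protocol, "pressure_protocol"),
            inherits(servo, "simulated_servo"), dt > 0)
  levels <- build_step_protocol(protocol)
  fpl <- max(1L, round(protocol$hold / dt))
  n <- nrow(levels) * fpl
  decay <- exp(-dt / servo$time_constant)
  osc <- protocol$oscillation

  time_s <- (seq_len(n) - 1L) * dt
  level_idx <- (seq_len(n) - 1L) %/% fpl + 1L
  base_sp <- levels$pressure_mmHg[level_idx]
  sp <- base_sp
  if (!is.null(osc)) {
    sp <- sp + osc$amplitude * sin(2 * pi * (osc$rate / 60) * time_s)
  }
  pressure <- numeric(n)
  p <- servo$current_pressure
  for (k in seq_len(n)) {
    p <- sp[k] + (p - sp[k]) * decay
    pressure[k] <- p
  }
  sensor <- pressure
  if (servo$sensor_noise_sd > 0) {
    sensor <- pressure + with_seed(seed, stats::rnorm(n, 0,
                                                      servo$sensor_noise_sd))
  }
  trans <- which(c(TRUE, diff(level_idx) != 0))
  events <- data.frame(time_s = time_s[trans], label = "pressure set",
                       pressure_mmHg = levels$pressure_mmHg[level_idx[trans]],
                       temperature_C = NA_real_,
                       stringsAsFactors = FALSE)
  out <- data.frame(time_s = time_s, level = level_idx,
                    setpoint_mmHg = base_sp, pressure_mmHg = pressure,
                    sensor_mmHg = sensor, stringsAsFactors = FALSE)
  attr(out, "events") <- events
  out
}

#' Run a fully simulated automated pressure-step experiment
#'
#' Closed loop against the simulated servo: at every frame the servo
#' pressure is advanced one first-order step toward the active setpoint,
#' the phantom vessel diameter is computed from the pressure-diameter
#' dynamics, a frame is rendered and tracked, and each level transition is
#' logged as a "pressure set" event. Given the same seeds the whole loop is
#' deterministic.
#'
#' @param protocol A [pressure_protocol()].
#' @param servo A [simulated_servo()].
#' @param dynamics Parameter list for the \code{pressure_curve} kind of
#'   [simulate_dynamics()] (\code{pressures} is supplied by the loop).
#' @param spec A [phantom_spec()] template (geometry \code{straight} or
#'   \code{strip}); its \code{od_track} and \code{n_frames} are overwritten
#'   by the loop.
#' @param line Optional [track_line()]; default: a horizontal ROI spanning
#'   the frame, suited to the default vertical phantom vessel.
#' @param params,track Detection and temporal-filter parameters.
#' @param dt Frame interval, s; default \code{spec$frame_interval}.
#' @param seed Seed for rendering noise and the sensor.
#' @return A [result_table()]: one record per frame with
#'   \code{pressure_mmHg} filled from the sensor, plus the event log.
#' @export
run_protocol <- function(protocol, servo, dynamics = list(), spec,
                         line = NULL, params = detect_params(),
                         track = track_params(), dt = NULL, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(dt)) dt <- spec$frame_interval
  trace <- simulate_servo_trace(protocol, servo, dt, seed = seed)
  dynamics$pressures <- trace$pressure_mmHg
  od <- simulate_dynamics("pressure_curve", dynamics)
  spec <- phantom_spec(geometry = spec$geometry,
                       frame_size = spec$frame_size, od_track = od,
                       id_fraction = spec$id_fraction[1],
                       modality = spec$modality,
                       intensities = spec$intensities,
                       axis_angle = spec$axis_angle,
                       psf_sigma = spec$psf_sigma, noise_sd = spec$noise_sd,
                       calibration = spec$calibration,
                       frame_interval = dt, seed = seed)
  if (is.null(line)) {
    w <- spec$frame_size[1]; h <- spec$frame_size[2]
    line <- track_line(1L, "roi_horizontal", x = 1, y = round(h * 0.3),
                       width = w - 2, height = round(h * 0.4),
                       mode = spec$modality)
  }
  rendered <- render_stack(spec)
  tab <- track_stack(rendered$stack, line, params, track)
  tab$records$pressure_mmHg <- trace$sensor_mmHg[tab$records$frame + 1L]
  tab$events <- attr(trace, "events")
  validate_result_table(tab)
  tab
}
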