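#' Piecewise-linear treadmill speed profile
#'
#' @param time numeric vector of breakpoint times (s), strictly increasing.
#' @param speed numeric vector of belt speeds (m/s) at those times, all >= 0.
#'   Speed is linearly interpolated between breakpoints and held constant
#'   after the last one.
#' @param trials optional data frame describing perturbation trials (one row
#'   per trial with columns `trial`, `type`, `magnitude`, `onset`,
#'   `plateau_start`, `plateau_end`, `end`); attached by
#'   [build_standard_protocol()] and consumed by [time_delays()].
#' @return an object of class `treadmill_profile`.
#' @export
treadmill_profile <- function(time, speed, trials = NULL) {
  if (length(time) != length(speed) || length(time) < 1L)
    stop("`time` and `speed` must be equal-length, non-empty", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  if (any(speed < 0))
    stop("speeds must be >= 0", call. = FALSE)
  structure(list(time = as.numeric(time), speed = as.numeric(speed),
                 trials = trials),
            class = "treadmill_profile")
}

#' Belt speed at given times
#'
#' @param profile a [treadmill_profile()].
#' @param t numeric vector of times (s). Times before the first breakpoint
#'   take the first speed; times after the last take the last speed.
#' @return numeric vector of speeds (m/s).
#' @export
speed_at <- function(profile, t) {
  stopifnot(inherits(profile, "treadmill_profile"))
  if (length(profile$time) == 1L) return(rep(profile$speed, length(t)))
  stats::approx(profile$time, profile$speed, xout = t, rule = 2)$y
}

#' Total duration of a profile
#' @param profile a [treadmill_profile()].
#' @return time (s) of the last breakpoint.
#' @export
profile_duration <- function(profile) {
  stopifnot(inherits(profile, "treadmill_profile"))
  max(profile$time)
}

#' Trial table of a protocol profile
#' @param profile a [treadmill_profile()].
#' @return the trial data frame attached by [build_standard_protocol()], or
#'   `NULL` for a profile without trials.
#' @export
protocol_trials <- function(profile) {
  stopifnot(inherits(profile, "treadmill_profile"))
  profile$trials
}

#' Standard treadmill speed-perturbation protocol
#'
#' Builds the experiment's belt-speed schedule: a ramp from standstill to the
#' baseline speed, then a block of speed-up trials followed by a block of
#' slow-down trials. Each magnitude in `deltas` (sorted ascending) is
#' repeated `reps` times consecutively, so the default gives three small,
#' three medium, and three large increases and then the same decreases —
#' eighteen trials in a fixed, non-randomized order. Each trial dwells
#' `dwell` seconds at baseline, ramps at `acceleration` to
#' `baseline_speed + delta` (or `- delta`), dwells `dwell` seconds there,
#' and ramps back. A final `dwell` at baseline closes the protocol.
#'
#' @param baseline_speed baseline belt speed, m/s (> 0).
#' @param deltas numeric vector of speed-change magnitudes, m/s; empty for a
#'   constant-speed profile after the initial ramp.
#' @param dwell time spent at each plateau, s (> 0).
#' @param acceleration magnitude of every speed ramp, m/s^2 (> 0).
#' @param reps number of consecutive repetitions of each magnitude.
#' @return a [treadmill_profile()] with a trial table (see
#'   [protocol_trials()]): `onset` is when the belt first leaves baseline
#'   and `end` when it regains it.
#' @export
build_standard_protocol <- function(baseline_speed = 1.4,
                                    deltas = c(0.1, 0.2, 0.3),
                                    dwell = 15,
                                    acceleration = 0.5,
                                    reps = 3L) {
  if (baseline_speed <= 0) stop("`baseline_speed` must be > 0", call. = FALSE)
  if (dwell <= 0) stop("`dwell` must be > 0", call. = FALSE)
  if (acceleration <= 0) stop("`acceleration` must be > 0", call. = FALSE)
  if (any(deltas <= 0)) stop("`deltas` must be > 0", call. = FALSE)

  time <- 0
  speed <- 0
  t <- baseline_speed / acceleration          # initial ramp 0 -> baseline
  time <- c(time, t); speed <- c(speed, baseline_speed)

  add_point <- function(dt_seg, v) {
    t <<- t + dt_seg
    time <<- c(time, t); speed <<- c(speed, v)
  }

  mags <- rep(sort(deltas), each = reps)
  trial_list <- list()
  i <- 0L
  for (sign in c(1, -1)) {
    for (mag in mags) {
      i <- i + 1L
      target <- baseline_speed + sign * mag
      if (target < 0) stop("trial target speed below 0", call. = FALSE)
      ramp <- mag / acceleration
      add_point(dwell, baseline_speed)        # dwell at baseline
      onset <- t
      add_point(ramp, target)                 # ramp away
      plateau_start <- t
      add_point(dwell, target)                # dwell at target
      plateau_end <- t
      add_point(ramp, baseline_speed)         # ramp back
      trial_list[[i]] <- data.frame(
        trial = i,
        type = if (sign > 0) "SU" else "SD",
        magnitude = mag,
        onset = onset,
        plateau_start = plateau_start,
        plateau_end = plateau_end,
        end = t)
    }
  }
  add_point(dwell, baseline_speed)            # closing dwell
  trials <- if (length(trial_list)) do.call(rbind, trial_list) else NULL
  treadmill_profile(time, speed, trials = trials)
}
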