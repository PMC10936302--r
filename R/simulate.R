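#' Simulate a labeled synthetic gait stream
#'
#' Generates multichannel joint-angle frames at a fixed sample interval while
#' the treadmill follows `profile`. At belt speed `v` the instantaneous cycle
#' duration is `T(v) = cycle_duration_at_reference * (reference_speed /
#' v)^cycle_speed_exponent` and the normalized cycle phase advances by
#' `dt / T(v)` per frame. The gait phase label follows the template's phase
#' fractions in the cyclic order LDS, LSS, RDS, RSS; the measurement vector
#' is the template trajectory at the current cycle phase, amplitude-scaled by
#' speed, plus one zero-mean Gaussian draw per frame. Frames at belt speed 0
#' are labeled `"stand"`; the cycle phase does not advance there and such
#' frames are excluded from model training and classification downstream.
#'
#' At constant speed the stream is cyclostationary: every revisit of the same
#' (phase, timestep) cell draws i.i.d. from the same Gaussian.
#'
#' @param template a [gait_template()].
#' @param profile a [treadmill_profile()]; scalars are also accepted and
#'   treated as a constant-speed profile.
#' @param duration stream length, s; defaults to the profile duration.
#' @param seed integer seed for the noise draws; `NULL` leaves the RNG state
#'   alone.
#' @param dt sample interval, s (default 0.01, i.e., 100 Hz).
#' @param start_phase cycle phase in `[0, 1)` at the first walking frame.
#' @return a `gait_stream`: a data frame with columns `time`, one column per
#'   channel, `phase` (`"LDS"`, `"LSS"`, `"RDS"`, `"RSS"`, or `"stand"`),
#'   `speed`, `contact_left`, `contact_right`, and a hidden `cycle_s` column
#'   with the true cycle phase; attributes `dt` and `channels`.
#' @export
simulate_gait <- function(template, profile, duration = NULL, seed = NULL,
                          dt = 0.01, start_phase = 0) {
  stopifnot(inherits(template, "gait_template"))
  if (is.numeric(profile) && length(profile) == 1L)
    profile <- treadmill_profile(0, profile)
  stopifnot(inherits(profile, "treadmill_profile"))
  if (is.null(duration)) duration <- profile_duration(profile)
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  time <- seq(0, duration, by = dt)
  n <- length(time)
  v <- speed_at(profile, time)
  walking <- v > 0
  Tv <- rep(NA_real_, n)
  Tv[walking] <- template$cycle_duration_at_reference *
    (template$reference_speed / v[walking])^template$cycle_speed_exponent
  inc <- ifelse(walking, dt / Tv, 0)
  # phase at frame i accumulates increments of frames 1..i-1
  s <- (start_phase + cumsum(c(0, inc[-n]))) %% 1

  # when a phase boundary falls exactly on a sample (e.g., a cycle of
  # exactly 103 frames), accumulated rounding must not flip the frame from
  # one side of the boundary to the other: snap to boundaries within 1e-9
  cuts <- cumsum(template$phase_fractions)
  for (b in c(0, cuts)) {
    hit <- abs(s - b) < 1e-9
    s[hit] <- b %% 1
  }
  phase <- GAIT_PHASES[findInterval(s, c(0, cuts[1:3])) ]
  phase[!walking] <- "stand"

  traj <- evaluate_template(template, s, ifelse(walking, v, template$reference_speed))
  noise <- MASS::mvrnorm(n, mu = rep(0, nrow(template$noise_covariance)),
                         Sigma = template$noise_covariance)
  if (n == 1L) noise <- matrix(noise, nrow = 1L)
  meas <- traj + noise

  out <- data.frame(time = time, meas, check.names = FALSE)
  out$phase <- phase
  out$speed <- v
  out$contact_left <- as.integer(phase %in% c("LDS", "LSS", "RDS", "stand"))
  out$contact_right <- as.integer(phase %in% c("RDS", "RSS", "LDS", "stand"))
  out$cycle_s <- s
  attr(out, "dt") <- dt
  attr(out, "channels") <- template$channel_names
  class(out) <- c("gait_stream", "data.frame")
  out
}

#' @export
`[.gait_stream` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "dt") <- attr(x, "dt")
    attr(out, "channels") <- intersect(attr(x, "channels"), names(out))
    class(out) <- class(x)
  }
  out
}

#' Channel columns of a gait stream
#' @param stream a `gait_stream` or compatible data frame.
#' @param channels optional channel names; defaults to the stream's
#'   `channels` attribute, else all `ch_*` columns.
#' @return numeric matrix of measurements, frames in rows.
#' @export
stream_measurements <- function(stream, channels = NULL) {
  if (is.null(channels)) channels <- attr(stream, "channels")
  if (is.null(channels)) channels <- grep("^ch_", names(stream), value = TRUE)
  if (!length(channels) || !all(channels %in% names(stream)))
    stop("cannot locate measurement channels in stream", call. = FALSE)
  as.matrix(stream[, channels, drop = FALSE])
}

#' Derive planar leg segment positions from joint angles
#'
#' Attaches per-leg hip, knee, and heel positions computed by planar
#' two-link forward kinematics from the hip and knee flexion channels. The
#' hip point translates forward at the belt speed (as if walking overground
#' at the belt speed); the second coordinate is vertical. Hip flexion is the
#' thigh angle from the downward vertical (forward positive); knee flexion
#' is the interior flexion between thigh and shank, so zero knee flexion
#' makes hip, knee, and heel collinear.
#'
#' @param stream a `gait_stream` whose template declared hip/knee roles.
#' @param template the generating [gait_template()] (for the channel roles).
#' @param thigh_length,shank_length segment lengths, m.
#' @param hip_height height of the hip joint above ground, m.
#' @return `stream` with 12 extra columns `{hip,knee,heel}_{l,r}_{x,z}`.
#' @export
derive_segment_positions <- function(stream, template,
                                     thigh_length = 0.45,
                                     shank_length = 0.45,
                                     hip_height = 0.95) {
  stopifnot(inherits(template, "gait_template"))
  roles <- template$roles
  need <- c("hip_l", "knee_l", "hip_r", "knee_r")
  if (is.null(roles) || !all(need %in% names(roles)))
    stop("template must declare hip and knee channel roles for both legs",
         call. = FALSE)
  meas <- stream_measurements(stream, template$channel_names)
  dt <- attr(stream, "dt")
  if (is.null(dt)) dt <- stats::median(diff(stream$time))
  hip_x <- cumsum(stream$speed * dt)
  hip_z <- rep(hip_height, nrow(stream))
  for (leg in c("l", "r")) {
    h <- meas[, roles[paste0("hip_", leg)]] * pi / 180
    k <- meas[, roles[paste0("knee_", leg)]] * pi / 180
    knee_x <- hip_x + thigh_length * sin(h)
    knee_z <- hip_z - thigh_length * cos(h)
    heel_x <- knee_x + shank_length * sin(h - k)
    heel_z <- knee_z - shank_length * cos(h - k)
    stream[[paste0("hip_", leg, "_x")]] <- hip_x
    stream[[paste0("hip_", leg, "_z")]] <- hip_z
    stream[[paste0("knee_", leg, "_x")]] <- knee_x
    stream[[paste0("knee_", leg, "_z")]] <- knee_z
    stream[[paste0("heel_", leg, "_x")]] <- heel_x
    stream[[paste0("heel_", leg, "_z")]] <- heel_z
  }
  stream
}

#' Write / read a gait stream as CSV
#'
#' Plain-text round-trip of the stream format: header row, `.` decimal
#' separator, one row per frame.
#'
#' @param stream a `gait_stream`.
#' @param path file path.
#' @return `write_gait_stream` returns `path` invisibly; `read_gait_stream`
#'   returns a `gait_stream`.
#' @export
write_gait_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_gait_stream
#' @param channels channel column names; defaults to every column that is
#'   not one of the reserved stream columns.
#' @export
read_gait_stream <- function(path, channels = NULL) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time" %in% names(out))
    stop("stream file lacks a `time` column", call. = FALSE)
  if (is.null(channels)) {
    reserved <- c("time", "phase", "speed", "contact_left", "contact_right",
                  "cycle_s")
    reserved <- c(reserved, grep("_(x|z)$", names(out), value = TRUE))
    channels <- setdiff(names(out), reserved)
  }
  attr(out, "dt") <- stats::median(diff(out$time))
  attr(out, "channels") <- channels
  class(out) <- c("gait_stream", "data.frame")
  out
}
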