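#' Periodic joint-angle template for the synthetic gait generator
#'
#' A `gait_template` describes one stride of constant-speed walking as a set
#' of low-order Fourier series over the normalized cycle phase
#' \eqn{s \in [0, 1)}, together with the statistical and timing structure the
#' intent-identification algorithm assumes: additive Gaussian measurement
#' noise, four gait phases (LDS, LSS, RDS, RSS) occupying fixed fractions of
#' the cycle, a cycle duration that shrinks with treadmill speed, and a
#' trajectory amplitude that grows with it.
#'
#' @param coefficients numeric matrix, one row per channel. Column 1 is the
#'   constant term; columns `2j` and `2j + 1` hold the cosine and sine
#'   coefficients of harmonic `j` (degrees). All channels share the harmonic
#'   order implied by the column count.
#' @param channel_names character vector naming each row.
#' @param roles optional named integer vector locating the channels needed
#'   for leg forward kinematics; names among `"hip_l"`, `"knee_l"`,
#'   `"hip_r"`, `"knee_r"`.
#' @param amplitude_speed_gain dimensionless gain per (m/s): trajectories are
#'   scaled by `1 + amplitude_speed_gain * (v - reference_speed)`.
#' @param noise_covariance symmetric positive-definite matrix (degrees^2) of
#'   the additive zero-mean Gaussian measurement noise.
#' @param phase_fractions length-4 numeric, fractions of the cycle spent in
#'   LDS, LSS, RDS, RSS (in that cyclic order); must sum to 1.
#' @param cycle_duration_at_reference full gait-cycle duration (s) at
#'   `reference_speed`.
#' @param reference_speed treadmill speed (m/s) at which the template was
#'   "recorded".
#' @param cycle_speed_exponent exponent of the cycle-duration speed law
#'   `T(v) = cycle_duration_at_reference * (reference_speed / v)^exponent`.
#'
#' @return an object of class `gait_template`.
#' @seealso [default_gait_template()], [simulate_gait()]
#' @export
gait_template <- function(coefficients,
                          channel_names = rownames(coefficients),
                          roles = NULL,
                          amplitude_speed_gain = 0.3,
                          noise_covariance = diag(nrow(coefficients)),
                          phase_fractions = c(LDS = 0.12, LSS = 0.38,
                                              RDS = 0.12, RSS = 0.38),
                          cycle_duration_at_reference = 1.03,
                          reference_speed = 1.4,
                          cycle_speed_exponent = 0.5) {
  coefficients <- as.matrix(coefficients)
  m <- nrow(coefficients)
  if (m < 1L || ncol(coefficients) %% 2L != 1L)
    stop("`coefficients` needs an odd number of columns: a0, then cos/sin pairs",
         call. = FALSE)
  if (is.null(channel_names)) channel_names <- paste0("ch_", seq_len(m))
  phase_fractions <- unname(phase_fractions)
  if (length(phase_fractions) != 4L || any(phase_fractions <= 0))
    stop("`phase_fractions` must be 4 positive values", call. = FALSE)
  if (abs(sum(phase_fractions) - 1) > 1e-12)
    stop("`phase_fractions` must sum to 1", call. = FALSE)
  noise_covariance <- as.matrix(noise_covariance)
  if (!isTRUE(all.equal(noise_covariance, t(noise_covariance),
                        tolerance = 1e-10)))
    stop("`noise_covariance` must be symmetric", call. = FALSE)
  if (nrow(noise_covariance) != m)
    stop("`noise_covariance` must be ", m, " x ", m, call. = FALSE)
  ev <- eigen(noise_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("`noise_covariance` must be positive definite", call. = FALSE)
  if (cycle_duration_at_reference <= 0)
    stop("`cycle_duration_at_reference` must be > 0", call. = FALSE)
  if (reference_speed <= 0)
    stop("`reference_speed` must be > 0", call. = FALSE)
  if (!is.null(roles)) {
    bad <- setdiff(names(roles), c("hip_l", "knee_l", "hip_r", "knee_r"))
    if (length(bad))
      stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(coefficients = coefficients,
         channel_names = channel_names,
         roles = roles,
         amplitude_speed_gain = amplitude_speed_gain,
         noise_covariance = noise_covariance,
         phase_fractions = phase_fractions,
         cycle_duration_at_reference = cycle_duration_at_reference,
         reference_speed = reference_speed,
         cycle_speed_exponent = cycle_speed_exponent),
    class = "gait_template")
}

# Fourier coefficients for a phase-shifted cosine:
# a * cos(2*pi*h*(s - off)) contributes a*cos(2*pi*h*off) to the cos term and
# a*sin(2*pi*h*off) to the sin term of harmonic h.
shifted_cos <- function(a, off, h, order) {
  out <- numeric(2L * order)
  out[2L * h - 1L] <- a * cos(2 * pi * h * off)
  out[2L * h] <- a * sin(2 * pi * h * off)
  out
}

#' Default four-channel hip/knee flexion template
#'
#' Left and right hip and knee flexion angles (degrees) over one stride,
#' calibrated so that a planar two-link leg driven by these angles yields a
#' virtual-leg vector whose angle with the vertical peaks at heel strike
#' (cycle phase 0 for the left leg) and bottoms out at toe-off (cycle phase
#' 0.62, the end of the left-stance interval under the default phase
#' fractions). Hip flexion spans about -11 to 24 degrees and knee flexion 0
#' to 60 degrees, typical of treadmill walking near 1.4 m/s. The right-leg
#' channels are the left-leg series shifted by half a cycle.
#'
#' @param noise_sd per-channel measurement noise standard deviation
#'   (degrees); the default 1 degree gives a diagonal noise covariance.
#' @param ... further arguments passed to [gait_template()].
#' @return a `gait_template` with channels
#'   `hip_l`, `knee_l`, `hip_r`, `knee_r`.
#' @export
default_gait_template <- function(noise_sd = 1, ...) {
  order <- 2L
  # hip:  h0 + h1 * cos(2*pi*(s - ho))
  h0 <- 6.0923; h1 <- 17.4538; ho <- 0.0756
  # knee: k0 - k1 * cos(2*pi*(s - ko)) - k2 * cos(4*pi*(s - ko2))
  k0 <- 27.9011; k1 <- 27.2185; ko <- 0.6020; k2 <- 7.1659; ko2 <- 0.4417
  hip_l <- c(h0, shifted_cos(h1, ho, 1L, order))
  knee_l <- c(k0, shifted_cos(-k1, ko, 1L, order) +
                shifted_cos(-k2, ko2, 2L, order))
  # right leg: substitute s + 1/2
  shift_half <- function(coef) {
    out <- coef
    for (h in seq_len(order)) {
      sgn <- if (h %% 2L == 1L) -1 else 1  # cos/sin(2*pi*h*(s + 1/2))
      out[2L * h] <- sgn * coef[2L * h]
      out[2L * h + 1L] <- sgn * coef[2L * h + 1L]
    }
    out
  }
  coef <- rbind(hip_l = hip_l, knee_l = knee_l,
                hip_r = shift_half(hip_l), knee_r = shift_half(knee_l))
  gait_template(coef,
                channel_names = c("hip_l", "knee_l", "hip_r", "knee_r"),
                roles = c(hip_l = 1L, knee_l = 2L, hip_r = 3L, knee_r = 4L),
                noise_covariance = diag(noise_sd^2, 4L),
                ...)
}

#' Evaluate a template's noise-free trajectories
#'
#' @param template a [gait_template()].
#' @param s numeric vector of cycle phases (wrapped to `[0, 1)`).
#' @param speed treadmill speed(s), m/s; scalar or one per element of `s`.
#'   The trajectory is scaled by
#'   `1 + amplitude_speed_gain * (speed - reference_speed)`.
#' @return numeric matrix, `length(s)` rows by `channel_count` columns.
#' @export
evaluate_template <- function(template, s, speed = template$reference_speed) {
  stopifnot(inherits(template, "gait_template"))
  coef <- template$coefficients
  order <- (ncol(coef) - 1L) %/% 2L
  s <- s %% 1
  basis <- matrix(1, length(s), ncol(coef))
  for (h in seq_len(order)) {
    basis[, 2L * h] <- cos(2 * pi * h * s)
    basis[, 2L * h + 1L] <- sin(2 * pi * h * s)
  }
  traj <- basis %*% t(coef)
  scale <- 1 + template$amplitude_speed_gain * (speed - template$reference_speed)
  traj <- traj * scale
  colnames(traj) <- template$channel_names
  traj
}

#' The four gait phases in cyclic order
#'
#' Left double support (left leg leading), left single support, right double
#' support, right single support. The cycle anchor is the left heel strike,
#' which begins LDS.
#' @export
GAIT_PHASES <- c("LDS", "LSS", "RDS", "RSS")

#' Cyclic successor of a gait phase
#' @param phase one of `"LDS"`, `"LSS"`, `"RDS"`, `"RSS"`.
#' @return the next phase in the cycle.
#' @export
next_phase <- function(phase) {
  i <- match(phase, GAIT_PHASES)
  if (any(is.na(i))) stop("unknown gait phase", call. = FALSE)
  GAIT_PHASES[i %% 4L + 1L]
}
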