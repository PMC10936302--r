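#' Virtual leg vector
#'
#' The virtual extended leg runs from the hip toward the ground: twice the
#' hip-to-knee vector plus the knee-to-heel vector. Its angle with the
#' vertical decreases monotonically while the leg is in stance and increases
#' while it swings, which makes it a robust stance/swing discriminator even
#' though it tracks no anatomical landmark.
#'
#' @param hip,knee,heel numeric coordinate vectors of equal length (the last
#'   coordinate is vertical), or matrices with one point per row.
#' @return `2 * (knee - hip) + (heel - knee)`, same shape as the inputs.
#' @export
virtual_leg_vector <- function(hip, knee, heel) {
  v <- 2 * (knee - hip) + (heel - knee)
  nrm <- if (is.matrix(v)) sqrt(rowSums(v^2)) else sqrt(sum(v^2))
  if (any(nrm < 1e-12))
    stop("degenerate geometry: virtual leg vector has zero length",
         call. = FALSE)
  v
}

#' Angle of a vector with the downward vertical
#'
#' The unsigned angle in `[0, 180]` degrees between `v` and the downward
#' vertical axis (last coordinate negative). With `forward` given, the angle
#' is signed by the sign of the vector's component along that axis, which
#' turns it into a sagittal-plane angle that rises monotonically through a
#' swing instead of folding at the vertical crossing.
#'
#' @param v numeric vector, or matrix with one vector per row; the last
#'   coordinate is vertical.
#' @param forward optional index of the forward (progression) axis for a
#'   signed angle.
#' @return angle(s) in degrees.
#' @export
vertical_angle <- function(v, forward = NULL) {
  if (!is.matrix(v)) v <- matrix(v, nrow = 1L, dimnames = NULL)
  d <- ncol(v)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12))
    stop("degenerate geometry: zero vector has no vertical angle",
         call. = FALSE)
  ang <- acos(pmin(1, pmax(-1, -v[, d] / nrm))) * 180 / pi
  if (!is.null(forward)) ang <- ang * ifelse(v[, forward] >= 0, 1, -1)
  if (length(ang) == 1L) ang[[1L]] else ang
}

#' Stance/swing detection from a leg-angle series
#'
#' Marks each frame of a uniformly sampled virtual-leg angle series as
#' `"swing"` while the (smoothed) angle is increasing and `"stance"` while
#' it is decreasing. The series is smoothed with a short causal moving
#' average, and a trend reversal must persist for `min_persist` consecutive
#' frames before the state switches, which suppresses chatter from
#' measurement noise. In the default batch mode the switch is backdated to
#' the raw-series extremum inside the detection window, so transition times
#' land on the true turning points; with `causal = TRUE` the state changes
#' only at the confirmation frame and never retroactively, as required for
#' streaming use.
#'
#' @param angle numeric vector, signed leg angle (degrees) sampled at `dt`.
#' @param smooth_window causal moving-average length, frames.
#' @param min_persist frames a reversal must persist before a switch.
#' @param causal if `TRUE`, never relabel already-emitted frames.
#' @return character vector, `"stance"` or `"swing"` per frame.
#' @export
detect_stance_swing <- function(angle, smooth_window = 5L, min_persist = 3L,
                                causal = FALSE) {
  n <- length(angle)
  if (n < smooth_window)
    stop("series shorter than the smoothing window", call. = FALSE)
  sm <- stats::filter(angle, rep(1 / smooth_window, smooth_window),
                      sides = 1)
  sm[seq_len(smooth_window - 1L)] <- cumsum(angle[seq_len(smooth_window - 1L)]) /
    seq_len(smooth_window - 1L)
  sm <- as.numeric(sm)
  dd <- c(0, diff(sm))
  dd[abs(dd) < 1e-10 * (1 + max(abs(angle)))] <- 0   # ignore rounding dust

  # initial state from the first nonzero smoothed trend; constant series
  # holds "stance" throughout (no reversals ever fire)
  first_dir <- dd[match(TRUE, dd != 0)]
  state <- if (!is.na(first_dir) && first_dir > 0) "swing" else "stance"
  out <- character(n)
  run <- 0L          # consecutive frames contradicting the current state
  run_start <- 0L
  for (i in seq_len(n)) {
    contra <- (state == "swing" && dd[i] < 0) ||
      (state == "stance" && dd[i] > 0)
    if (contra) {
      if (run == 0L) run_start <- i
      run <- run + 1L
    } else if (dd[i] != 0) run <- 0L
    out[i] <- state
    if (run >= min_persist) {
      state <- if (state == "swing") "stance" else "swing"
      if (causal) {
        out[i] <- state
      } else {
        # backdate to the raw extremum just before the reversal run
        lo <- max(1L, run_start - smooth_window)
        seg <- angle[lo:i]
        ext <- lo - 1L +
          (if (state == "swing") which.min(seg) else which.max(seg))
        out[ext:i] <- state
      }
      run <- 0L
    }
  }
  out
}

#' Gait phase from per-leg stance/swing states
#'
#' One leg in stance gives that leg's single-support phase. With both legs
#' in stance the phase is the double support of the leading leg, taken as
#' the leg that entered stance most recently (a heel strike opens a double
#' support). With both legs in swing — possible under noise, as true flight
#' is outside the model — the previous phase is held.
#'
#' @param left,right `"stance"` or `"swing"`.
#' @param previous_phase the phase at the previous frame, or `NULL` at
#'   stream start.
#' @param leading `"left"` or `"right"`: which leg entered stance most
#'   recently (needed only when both legs are in stance).
#' @return one of `"LDS"`, `"LSS"`, `"RDS"`, `"RSS"`.
#' @export
assign_phase <- function(left, right, previous_phase = NULL, leading = NULL) {
  if (left == "stance" && right == "swing") return("LSS")
  if (right == "stance" && left == "swing") return("RSS")
  if (left == "stance" && right == "stance") {
    if (!is.null(leading)) return(if (leading == "left") "LDS" else "RDS")
    if (is.null(previous_phase))
      stop("unresolved phase: both legs in stance at stream start with no ",
           "leading-leg information", call. = FALSE)
    return(previous_phase)
  }
  if (is.null(previous_phase))
    stop("unresolved phase: both legs in swing at stream start",
         call. = FALSE)
  previous_phase
}

#' Within-phase timestep tracking
#'
#' The timestep index `k` counts sample intervals since the current phase
#' began: it is 1 on the first frame of a phase, increments by 1 per frame
#' while the phase persists, and resets to 1 on a phase change.
#'
#' @param current_phase phase at this frame.
#' @param previous list with `phase` and `k` from the previous frame, or
#'   `NULL` at stream start.
#' @param dt sample interval, s (> 0).
#' @return list with `phase` and `k`.
#' @export
track_timestep <- function(current_phase, previous = NULL, dt = 0.01) {
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (is.null(previous) || !identical(previous$phase, current_phase))
    return(list(phase = current_phase, k = 1L))
  list(phase = current_phase, k = previous$k + 1L)
}

#' Timestep index from elapsed time
#'
#' Bins an elapsed time since the phase began to the nearest sample-grid
#' cell. A phase boundary falls between frames, so the first in-phase frame
#' sits about one `dt` after it and maps to `k = 1`.
#'
#' @param elapsed time since the phase began, s.
#' @param dt sample interval, s.
#' @return integer timestep `k >= 1`.
#' @export
timestep_from_elapsed <- function(elapsed, dt = 0.01) {
  pmax(1L, as.integer(round(elapsed / dt)))
}

#' Segment a stream into gait phases and timesteps
#'
#' Assigns every frame a gait phase and within-phase timestep. Foot-contact
#' flags (`contact_left`, `contact_right`), when present, are used directly;
#' otherwise the phase is inferred from leg segment positions via the
#' virtual-leg vector and stance/swing trend detection. Frames at belt
#' speed 0 (when a `speed` column is present) are labeled `"stand"` with
#' `k = NA` and never contribute to training or classification.
#'
#' @param stream a `gait_stream` or data frame with either contact flags or
#'   `{hip,knee,heel}_{l,r}_{x,z}` position columns.
#' @param use character: `"auto"` (contacts preferred), `"contacts"`, or
#'   `"positions"`.
#' @param smooth_window,min_persist,causal trend-detection controls for the
#'   kinematic path; see [detect_stance_swing()].
#' @param forward_axis index of the progression axis in the position columns.
#' @return data frame with columns `phase` and `k`, one row per frame.
#'   Frames before the phase can first be resolved carry `NA`.
#' @export
segment_stream <- function(stream, use = c("auto", "contacts", "positions"),
                           smooth_window = 5L, min_persist = 3L,
                           causal = FALSE, forward_axis = 1L) {
  use <- match.arg(use)
  has_contacts <- all(c("contact_left", "contact_right") %in% names(stream))
  pos_cols <- as.vector(outer(c("hip", "knee", "heel"),
                              c("l", "r"), function(a, b)
                                paste0(a, "_", b))) # base names
  has_pos <- all(paste0(rep(pos_cols, each = 2), c("_x", "_z")) %in%
                   names(stream))
  if (use == "auto") use <- if (has_contacts) "contacts" else "positions"
  if (use == "contacts" && !has_contacts)
    stop("stream has no contact flags", call. = FALSE)
  if (use == "positions" && !has_pos)
    stop("stream has neither contact flags nor leg positions", call. = FALSE)

  n <- nrow(stream)
  standing <- if ("speed" %in% names(stream)) stream$speed <= 0 else
    rep(FALSE, n)

  if (use == "contacts") {
    left <- ifelse(stream$contact_left > 0, "stance", "swing")
    right <- ifelse(stream$contact_right > 0, "stance", "swing")
  } else {
    ang <- list()
    for (leg in c("l", "r")) {
      cols <- function(seg) as.matrix(
        stream[, paste0(seg, "_", leg, "_", c("x", "z"))])
      vl <- virtual_leg_vector(cols("hip"), cols("knee"), cols("heel"))
      ang[[leg]] <- vertical_angle(vl, forward = forward_axis)
    }
    left <- detect_stance_swing(ang$l, smooth_window, min_persist, causal)
    right <- detect_stance_swing(ang$r, smooth_window, min_persist, causal)
  }

  phase <- character(n)
  k <- rep(NA_integer_, n)
  prev <- NULL
  prev_state <- c(left = NA_character_, right = NA_character_)
  leading <- NULL
  pk <- NULL
  for (i in seq_len(n)) {
    if (standing[i]) {
      phase[i] <- "stand"
      prev <- NULL; pk <- NULL; leading <- NULL
      prev_state <- c(left = NA_character_, right = NA_character_)
      next
    }
    if (!is.na(prev_state[["left"]])) {
      if (left[i] == "stance" && prev_state[["left"]] == "swing")
        leading <- "left"
      if (right[i] == "stance" && prev_state[["right"]] == "swing")
        leading <- "right"
    }
    ph <- tryCatch(
      assign_phase(left[i], right[i], previous_phase = prev,
                   leading = if (left[i] == "stance" &&
                                 right[i] == "stance") leading else NULL),
      error = function(e) NA_character_)
    phase[i] <- ph
    if (!is.na(ph)) {
      pk <- track_timestep(ph, if (i > 1L && !is.null(pk) &&
                                   !is.na(phase[i - 1L]) &&
                                   phase[i - 1L] != "stand") pk else NULL)
      k[i] <- pk$k
      prev <- ph
    }
    prev_state <- c(left = left[i], right = right[i])
  }
  data.frame(phase = phase, k = k)
}
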