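#' Classifier configuration
#'
#' Tunables of the real-time intent classifier. The default squared-distance
#' threshold 13.5 corresponds to a chi-squared CDF of 0.99 with four
#' measurement channels and sits at a roughly equal trade-off between
#' detection delay and F1-score; the squared-distance signal is smoothed by
#' a first-order low-pass Butterworth filter with a cutoff near 1.2 Hz
#' before the threshold test.
#'
#' @param squared_md_threshold flag a speed-intent change when the filtered
#'   squared Mahalanobis distance exceeds this (> 0).
#' @param filter_cutoff low-pass cutoff, Hz; must lie below the Nyquist
#'   frequency `1 / (2 dt)`.
#' @param dt sample interval, s.
#' @param timing_std_multiplier phase-timing mismatches larger than this
#'   multiple of the training-set timing standard deviation raise a flag.
#' @param ridge covariance regularization passed to
#'   [squared_mahalanobis()], degrees^2.
#' @param reference_phase phase whose onset marks a new gait cycle.
#' @return a `classifier_config`.
#' @export
classifier_config <- function(squared_md_threshold = 13.5,
                              filter_cutoff = 1.2,
                              dt = 0.01,
                              timing_std_multiplier = 1,
                              ridge = 1e-6,
                              reference_phase = "LDS") {
  if (squared_md_threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (filter_cutoff <= 0 || filter_cutoff >= 1 / (2 * dt))
    stop("`filter_cutoff` must lie in (0, Nyquist)", call. = FALSE)
  if (timing_std_multiplier <= 0) stop("multiplier must be > 0", call. = FALSE)
  structure(list(squared_md_threshold = squared_md_threshold,
                 filter_cutoff = filter_cutoff, dt = dt,
                 timing_std_multiplier = timing_std_multiplier,
                 ridge = ridge, reference_phase = reference_phase),
            class = "classifier_config")
}

#' Streaming first-order low-pass Butterworth filter
#'
#' `new_lowpass` discretizes a first-order Butterworth low-pass (bilinear
#' transform, via [signal::butter()]) and returns its state; `lowpass_step`
#' advances it by one sample. The state is initialized to the first input so
#' a constant signal passes through unchanged from the first step (DC gain
#' is exactly 1).
#'
#' @param cutoff cutoff frequency, Hz (below Nyquist).
#' @param dt sample interval, s.
#' @return `new_lowpass`: a filter-state list; `lowpass_step`: list with the
#'   updated `state` and the filtered `value`.
#' @export
new_lowpass <- function(cutoff, dt) {
  if (cutoff <= 0 || cutoff >= 1 / (2 * dt))
    stop("`cutoff` must lie in (0, Nyquist)", call. = FALSE)
  bt <- signal::butter(1, 2 * cutoff * dt, type = "low")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a),
       x1 = NA_real_, y1 = NA_real_)
}

#' @rdname new_lowpass
#' @param state a filter state from `new_lowpass` or a previous step.
#' @param value raw input sample.
#' @export
lowpass_step <- function(state, value) {
  if (is.na(state$y1)) {           # initialize at first input: no transient
    state$x1 <- value; state$y1 <- value
    return(list(state = state, value = value))
  }
  y <- state$b[1] * value + state$b[2] * state$x1 - state$a[2] * state$y1
  state$x1 <- value; state$y1 <- y
  list(state = state, value = y)
}

#' Phase-timing mismatch and cycle-speed questions
#'
#' The three timing questions of the classifier. Question A: has the current
#' phase already outlasted the model (current timestep exceeds the model's
#' timestep count for this phase by more than `multiplier` training standard
#' deviations)? Question B: did the just-completed phase finish short of the
#' model by more than that margin? Question C: was the most recently
#' completed gait cycle faster or slower than the training mean?
#'
#' @param k current within-phase timestep (A) .
#' @param model_max_k the model's timestep count for the phase.
#' @param sd_k training-set standard deviation of that phase's timestep
#'   count.
#' @param multiplier margin multiplier (default 1 standard deviation).
#' @return `question_a`, `question_b`: logical flag. `question_c`: one of
#'   `"faster"`, `"slower"`, `"unchanged"`.
#' @export
question_a <- function(k, model_max_k, sd_k, multiplier = 1) {
  (k - model_max_k) > multiplier * sd_k
}

#' @rdname question_a
#' @param final_k the timestep count the previous phase ended with.
#' @export
question_b <- function(final_k, model_max_k, sd_k, multiplier = 1) {
  (model_max_k - final_k) > multiplier * sd_k
}

#' @rdname question_a
#' @param completed_cycle_duration duration of the most recently completed
#'   gait cycle, s.
#' @param cycle_mean mean training-set cycle duration, s.
#' @export
question_c <- function(completed_cycle_duration, cycle_mean) {
  if (completed_cycle_duration < cycle_mean) "faster"
  else if (completed_cycle_duration > cycle_mean) "slower"
  else "unchanged"
}

#' Fresh classifier state
#'
#' @param model a `gait_model`.
#' @param config a [classifier_config()].
#' @return a `classifier_state` ready for [classify_step()].
#' @export
new_classifier_state <- function(model, config = classifier_config()) {
  list(filter = new_lowpass(config$filter_cutoff, config$dt),
       filtered = NA_real_,
       prev_phase = NULL, k = 0L,
       qb_flag = FALSE,
       cycle_dir = "none",
       frames_since_cycle_start = NA_integer_)
}

#' One step of the real-time intent classifier
#'
#' Scores `x` against the model cell for the current (phase, timestep) when
#' one exists, smooths the squared distance with the streaming low-pass
#' filter, and flags a speed-intent change when (a) the filtered value
#' exceeds the threshold, (b) the current phase has outlasted its model
#' timing margin (Question A), or (c) the previous phase ended short of it
#' (Question B, held until the current phase ends). A flagged frame is
#' labeled `"SU"` if the most recently completed gait cycle was faster than
#' the training mean, `"SD"` if slower, and `"NC"` (with a
#' `type_unresolved` diagnostic) if no cycle has completed or the last one
#' matched exactly. Beyond the model's timestep range no distance exists;
#' the filter state is held frozen and only the timing flags can trigger.
#'
#' @param state a `classifier_state`.
#' @param x measurement vector for this frame.
#' @param phase gait phase of this frame.
#' @param k within-phase timestep of this frame.
#' @param model a `gait_model`.
#' @param config a [classifier_config()].
#' @return list with updated `state`, the `label` (`"SU"`, `"SD"`, `"NC"`),
#'   and a `diag` list (`d2`, `filtered`, `trigger`, `cycle_dir`,
#'   `type_unresolved`).
#' @export
classify_step <- function(state, x, phase, k, model,
                          config = classifier_config()) {
  new_phase_entered <- is.null(state$prev_phase) ||
    !identical(phase, state$prev_phase)
  if (new_phase_entered && !is.null(state$prev_phase)) {
    # Question B on the phase that just completed
    pt <- model$timing[[state$prev_phase]]
    state$qb_flag <- question_b(state$k, model$max_k[[state$prev_phase]],
                                pt$sd_k, config$timing_std_multiplier)
    # cycle bookkeeping at each reference-phase onset
    if (identical(phase, config$reference_phase)) {
      if (!is.na(state$frames_since_cycle_start) &&
          !is.na(model$timing$cycle_mean)) {
        dur <- state$frames_since_cycle_start * config$dt
        state$cycle_dir <- question_c(dur, model$timing$cycle_mean)
      }
      state$frames_since_cycle_start <- 0L
    }
  } else if (new_phase_entered &&
             identical(phase, config$reference_phase)) {
    state$frames_since_cycle_start <- 0L
  }
  if (!is.na(state$frames_since_cycle_start))
    state$frames_since_cycle_start <- state$frames_since_cycle_start + 1L

  d2 <- NA_real_
  in_model <- k <= model$max_k[[phase]]
  if (in_model) {
    cell <- model$cells[[phase]][[k]]
    if (is.null(cell))
      stop("internal inconsistency: missing cell (", phase, ", ", k,
           ") inside the model's contiguous range", call. = FALSE)
    d2 <- squared_mahalanobis(x, cell, ridge = config$ridge)
    st <- lowpass_step(state$filter, d2)
    state$filter <- st$state
    state$filtered <- st$value
  }
  qa <- question_a(k, model$max_k[[phase]],
                   model$timing[[phase]]$sd_k,
                   config$timing_std_multiplier)
  md_flag <- !is.na(state$filtered) &&
    state$filtered > config$squared_md_threshold

  trigger <- if (md_flag) "md" else if (qa) "question_a" else
    if (state$qb_flag) "question_b" else "none"
  flagged <- trigger != "none"
  type_unresolved <- flagged && !(state$cycle_dir %in% c("faster", "slower"))
  label <- if (!flagged || type_unresolved) "NC" else
    if (state$cycle_dir == "faster") "SU" else "SD"

  state$prev_phase <- phase
  state$k <- k
  list(state = state, label = label,
       diag = list(d2 = d2, filtered = state$filtered, trigger = trigger,
                   cycle_dir = state$cycle_dir,
                   type_unresolved = type_unresolved))
}

#' Run the intent classifier over a stream
#'
#' Drives [classify_step()] across every frame: segments the stream (foot
#' contacts preferred; the strictly causal kinematic path otherwise, so the
#' output at a frame never depends on later frames), scores, filters, and
#' labels. Standing frames and frames whose phase cannot yet be resolved
#' receive `NA` labels and are excluded from evaluation.
#'
#' @param stream a `gait_stream` (or data frame with `time` + channels).
#' @param model a `gait_model`.
#' @param config a [classifier_config()].
#' @param segmentation optional precomputed data frame with `phase`, `k`.
#' @return data frame with one row per frame: `time`, `phase`, `k`, `d2`
#'   (raw squared distance, `NA` outside the model range), `filtered`,
#'   `trigger`, `cycle_dir`, `label`.
#' @export
run_intent <- function(stream, model, config = classifier_config(),
                       segmentation = NULL) {
  if (is.null(segmentation)) segmentation <- segment_stream(stream, causal = TRUE)
  meas <- stream_measurements(stream)
  n <- nrow(meas)
  stopifnot(nrow(segmentation) == n)
  if (n == 0L)
    return(data.frame(time = numeric(0), phase = character(0),
                      k = integer(0), d2 = numeric(0),
                      filtered = numeric(0), trigger = character(0),
                      cycle_dir = character(0), label = character(0)))

  # precompute per-cell inverse Cholesky factors once (ridge included)
  inv <- lapply(GAIT_PHASES, function(p)
    lapply(model$cells[[p]], function(cell) {
      S <- cell$Sigma + diag(config$ridge, model$m)
      R <- tryCatch(chol(S), error = function(e)
        stop("ill-conditioned cell covariance in phase ", p, call. = FALSE))
      backsolve(R, diag(model$m))       # S^-1 = RinvT %*% Rinv ... see below
    }))
  names(inv) <- GAIT_PHASES

  state <- new_classifier_state(model, config)
  label <- character(n); trigger <- character(n); cdir <- character(n)
  d2v <- rep(NA_real_, n); fv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- segmentation$phase[i]; k <- segmentation$k[i]
    if (is.na(p) || !(p %in% GAIT_PHASES) || is.na(k)) {
      label[i] <- NA_character_; trigger[i] <- NA_character_
      cdir[i] <- NA_character_
      next
    }
    res <- classify_step_fast(state, meas[i, ], p, k, model, config, inv)
    state <- res$state
    label[i] <- res$label
    trigger[i] <- res$diag$trigger
    cdir[i] <- res$diag$cycle_dir
    d2v[i] <- res$diag$d2
    fv[i] <- res$diag$filtered
  }
  out <- data.frame(time = stream$time, phase = segmentation$phase,
                    k = segmentation$k, d2 = d2v, filtered = fv,
                    trigger = trigger, cycle_dir = cdir, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("intent_output", "data.frame")
  out
}

# classify_step with precomputed inverse Cholesky factors (hot loop)
classify_step_fast <- function(state, x, phase, k, model, config, inv) {
  new_phase_entered <- is.null(state$prev_phase) ||
    phase != state$prev_phase
  if (new_phase_entered && !is.null(state$prev_phase)) {
    pt <- model$timing[[state$prev_phase]]
    state$qb_flag <- (model$max_k[[state$prev_phase]] - state$k) >
      config$timing_std_multiplier * pt$sd_k
    if (phase == config$reference_phase) {
      if (!is.na(state$frames_since_cycle_start) &&
          !is.na(model$timing$cycle_mean)) {
        dur <- state$frames_since_cycle_start * config$dt
        state$cycle_dir <- question_c(dur, model$timing$cycle_mean)
      }
      state$frames_since_cycle_start <- 0L
    }
  } else if (new_phase_entered && phase == config$reference_phase) {
    state$frames_since_cycle_start <- 0L
  }
  if (!is.na(state$frames_since_cycle_start))
    state$frames_since_cycle_start <- state$frames_since_cycle_start + 1L

  d2 <- NA_real_
  if (k <= model$max_k[[phase]]) {
    Rinv <- inv[[phase]][[k]]
    z <- crossprod(Rinv, x - model$cells[[phase]][[k]]$mu)
    d2 <- sum(z * z)
    st <- lowpass_step(state$filter, d2)
    state$filter <- st$state
    state$filtered <- st$value
  }
  qa <- (k - model$max_k[[phase]]) >
    config$timing_std_multiplier * model$timing[[phase]]$sd_k
  md_flag <- !is.na(state$filtered) &&
    state$filtered > config$squared_md_threshold
  trigger <- if (md_flag) "md" else if (qa) "question_a" else
    if (state$qb_flag) "question_b" else "none"
  flagged <- trigger != "none"
  type_unresolved <- flagged && !(state$cycle_dir %in% c("faster", "slower"))
  label <- if (!flagged || type_unresolved) "NC" else
    if (state$cycle_dir == "faster") "SU" else "SD"
  state$prev_phase <- phase
  state$k <- k
  list(state = state, label = label,
       diag = list(d2 = d2, filtered = state$filtered, trigger = trigger,
                   cycle_dir = state$cycle_dir,
                   type_unresolved = type_unresolved))
}
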