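#' Gaussian cell: running Gaussian estimate for one (phase, timestep)
#'
#' Each cell holds the observation count `n`, mean vector `mu`, and
#' maximum-likelihood (divide-by-n) covariance `Sigma` of all measurement
#' vectors seen at one (gait phase, timestep) slot. [update_cell()] folds in
#' one observation with a single-pass recursive update that reproduces the
#' batch estimates exactly.
#'
#' @param x numeric measurement vector (first observation).
#' @return a `gaussian_cell`.
#' @export
new_gaussian_cell <- function(x) {
  x <- as.numeric(x)
  m <- length(x)
  structure(list(n = 1L, mu = x, Sigma = matrix(0, m, m)),
            class = "gaussian_cell")
}

#' @rdname new_gaussian_cell
#' @param cell an existing `gaussian_cell`, or `NULL` to start one.
#' @export
update_cell <- function(cell, x) {
  x <- as.numeric(x)
  if (is.null(cell)) return(new_gaussian_cell(x))
  if (length(x) != length(cell$mu))
    stop("measurement has length ", length(x), ", cell expects ",
         length(cell$mu), call. = FALSE)
  n <- cell$n
  delta <- x - cell$mu
  mu <- cell$mu + delta / (n + 1)
  # MLE covariance: Sigma_{n+1} = (n Sigma_n + n/(n+1) delta delta') / (n+1)
  Sigma <- (n * cell$Sigma + (n / (n + 1)) * tcrossprod(delta)) / (n + 1)
  structure(list(n = n + 1L, mu = mu, Sigma = Sigma),
            class = "gaussian_cell")
}

#' Squared Mahalanobis distance to a Gaussian cell
#'
#' Evaluates `(x - mu)' (Sigma + ridge I)^{-1} (x - mu)` through a Cholesky
#' solve. The ridge keeps cells with few observations (or noise-free
#' training data) invertible; the default is negligible against
#' degree-scale variances.
#'
#' @param x numeric measurement vector.
#' @param cell a `gaussian_cell`.
#' @param ridge nonnegative diagonal regularization, degrees^2.
#' @return nonnegative scalar.
#' @export
squared_mahalanobis <- function(x, cell, ridge = 1e-6) {
  x <- as.numeric(x)
  if (length(x) != length(cell$mu))
    stop("dimension mismatch between `x` and cell", call. = FALSE)
  S <- cell$Sigma
  if (ridge > 0) S <- S + diag(ridge, nrow(S))
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R))
    stop("ill-conditioned cell covariance (even after ridge)", call. = FALSE)
  z <- backsolve(R, x - cell$mu, transpose = TRUE)
  sum(z^2)
}

#' Chi-squared CDF and inverse for threshold calibration
#'
#' Squared Mahalanobis distances of samples drawn from an m-variate Gaussian
#' follow a chi-squared distribution with m degrees of freedom, so the CDF
#' maps a squared-distance threshold to the fraction of in-distribution
#' samples that fall below it. With four measurement channels, a squared
#' distance of 13.5 sits at CDF 0.99: frames farther from the cell mean than
#' 99% of in-model data indicate a changed speed intent.
#'
#' @param d2 nonnegative squared distance(s).
#' @param dof degrees of freedom (number of measurement channels), >= 1.
#' @return `chi2_cdf`: probability; `threshold_for_cdf`: the squared-distance
#'   threshold whose CDF equals `p`.
#' @export
chi2_cdf <- function(d2, dof) {
  if (any(dof < 1) || any(dof != round(dof)))
    stop("`dof` must be a positive integer", call. = FALSE)
  if (any(d2 < 0)) stop("`d2` must be >= 0", call. = FALSE)
  stats::pchisq(d2, df = dof)
}

#' @rdname chi2_cdf
#' @param p probability in (0, 1).
#' @export
threshold_for_cdf <- function(p, dof) {
  if (any(dof < 1) || any(dof != round(dof)))
    stop("`dof` must be a positive integer", call. = FALSE)
  if (any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  stats::qchisq(p, df = dof)
}

#' Fit the cyclostationary gait model
#'
#' Builds one Gaussian cell per (gait phase, timestep) from constant-speed
#' training frames, plus the phase/cycle timing statistics the intent
#' classifier needs. Timing statistics come from complete phase occurrences
#' only (the first occurrence, whose start may be unseen, and the trailing
#' truncated occurrence are dropped); a gait cycle runs from one start of
#' the reference phase to the next.
#'
#' @param frames numeric matrix of measurements (frames in rows), or a
#'   `gait_stream`.
#' @param segmentation data frame with `phase` and `k` per frame, as from
#'   [segment_stream()]; defaults to segmenting `frames` itself. Frames with
#'   `NA` or `"stand"` phase are skipped.
#' @param dt sample interval, s.
#' @param reference_phase phase whose onset anchors a gait cycle.
#' @param min_cell_n cells with fewer observations are flagged (they remain
#'   usable through the ridge).
#' @return a `gait_model`: list with channel count `m`, `dt`, `cells` (per
#'   phase, a list over `k` of `gaussian_cell`s), `max_k`, `timing` (per
#'   phase mean/sd of timestep counts; `cycle_mean`, `cycle_sd` in s),
#'   `flags`, and `meta`.
#' @export
fit_gait_model <- function(frames, segmentation = NULL, dt = 0.01,
                           reference_phase = "LDS", min_cell_n = 3L) {
  if (inherits(frames, "gait_stream")) {
    if (is.null(segmentation)) segmentation <- segment_stream(frames)
    if (!is.null(attr(frames, "dt"))) dt <- attr(frames, "dt")
    meas <- stream_measurements(frames)
  } else {
    meas <- as.matrix(frames)
    if (is.null(segmentation))
      stop("`segmentation` is required when `frames` is a bare matrix",
           call. = FALSE)
  }
  stopifnot(nrow(meas) == nrow(segmentation))
  ok <- !is.na(segmentation$phase) & segmentation$phase %in% GAIT_PHASES &
    !is.na(segmentation$k)
  if (!any(ok)) stop("no usable walking frames to fit on", call. = FALSE)
  phase <- segmentation$phase[ok]
  k <- segmentation$k[ok]
  meas <- meas[ok, , drop = FALSE]
  m <- ncol(meas)

  cells <- stats::setNames(vector("list", 4L), GAIT_PHASES)
  for (p in GAIT_PHASES) cells[[p]] <- list()
  for (i in seq_len(nrow(meas))) {
    p <- phase[i]; ki <- k[i]
    prev <- if (ki <= length(cells[[p]])) cells[[p]][[ki]] else NULL
    cells[[p]][[ki]] <- update_cell(prev, meas[i, ])
  }

  # phase occurrences: runs of constant phase in the kept frames
  r <- rle(phase)
  n_runs <- length(r$values)
  keep <- seq_len(n_runs)
  keep <- keep[keep > 1L & keep < n_runs]   # drop partial first/last
  occ_phase <- r$values[keep]
  occ_len <- r$lengths[keep]

  timing <- list()
  flags <- character(0)
  for (p in GAIT_PHASES) {
    len <- occ_len[occ_phase == p]
    if (length(len) == 0L) {
      timing[[p]] <- list(mean_k = NA_real_, sd_k = NA_real_, n_occ = 0L)
      flags <- c(flags, paste0("no complete occurrence of ", p))
    } else {
      sdk <- if (length(len) >= 2L) stats::sd(len) else 0
      if (length(len) < 2L)
        flags <- c(flags, paste0("single occurrence of ", p,
                                 ": timing sd set to 0"))
      timing[[p]] <- list(mean_k = mean(len), sd_k = sdk,
                          n_occ = length(len))
    }
  }

  # cycle durations between successive reference-phase onsets
  starts <- which(r$values == reference_phase)
  onset_idx <- cumsum(c(1L, r$lengths))[starts]   # frame index of each onset
  cyc <- diff(onset_idx) * dt
  if (length(cyc) >= 1L) {
    cycle_mean <- mean(cyc)
    cycle_sd <- if (length(cyc) >= 2L) stats::sd(cyc) else 0
  } else {
    cycle_mean <- NA_real_; cycle_sd <- 0
    flags <- c(flags, "fewer than two reference-phase onsets: no cycle stats")
  }
  timing$cycle_mean <- cycle_mean
  timing$cycle_sd <- cycle_sd
  timing$n_cycles <- length(cyc)

  max_k <- vapply(cells, length, integer(1))
  for (p in GAIT_PHASES) {
    ns <- vapply(cells[[p]], function(c) if (is.null(c)) 0L else c$n,
                 integer(1))
    if (any(ns == 0L))
      stop("internal error: non-contiguous timesteps in phase ", p,
           call. = FALSE)
    if (any(ns < min_cell_n))
      flags <- c(flags, paste0(sum(ns < min_cell_n), " cell(s) in ", p,
                               " with fewer than ", min_cell_n,
                               " observations"))
  }

  structure(list(m = m, dt = dt, cells = cells, max_k = max_k,
                 timing = timing, reference_phase = reference_phase,
                 flags = flags,
                 meta = list(frames = nrow(meas),
                             duration = nrow(meas) * dt,
                             created = format(Sys.time(), "%Y-%m-%d"))),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat("Cyclostationary gait model:", x$m, "channels at dt =", x$dt, "s\n")
  cat("  timesteps per phase:",
      paste(sprintf("%s=%d", GAIT_PHASES, x$max_k[GAIT_PHASES]),
            collapse = ", "), "\n")
  cat(sprintf("  cycle duration %.3f +/- %.3f s over %d training cycles\n",
              x$timing$cycle_mean, x$timing$cycle_sd, x$timing$n_cycles))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Save or load a gait model as structured text
#'
#' Lossless JSON round-trip of every model field, with matrices stored as
#' row-major lists and a format version tag.
#'
#' @param model a `gait_model`.
#' @param path file path.
#' @return `save_gait_model` returns `path` invisibly; `load_gait_model`
#'   returns the restored `gait_model`.
#' @export
save_gait_model <- function(model, path) {
  stopifnot(inherits(model, "gait_model"))
  ser <- list(
    format = "gaitintent-model", version = "1.0",
    m = model$m, dt = model$dt, reference_phase = model$reference_phase,
    max_k = as.list(model$max_k), timing = model$timing,
    flags = model$flags, meta = model$meta,
    cells = lapply(model$cells, function(ph)
      lapply(ph, function(cell)
        list(n = cell$n, mu = cell$mu,
             Sigma = as.vector(t(cell$Sigma))))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname save_gait_model
#' @export
load_gait_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(ser$format, "gaitintent-model"))
    stop("not a gait model file", call. = FALSE)
  if (!identical(ser$version, "1.0"))
    stop("unsupported model format version: ", ser$version, call. = FALSE)
  need <- c("m", "dt", "cells", "max_k", "timing")
  miss <- setdiff(need, names(ser))
  if (length(miss))
    stop("model file is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- ser$m
  cells <- lapply(ser$cells, function(ph)
    lapply(ph, function(cell) {
      mu <- as.numeric(cell$mu)
      sig <- as.numeric(cell$Sigma)
      if (length(mu) != m || length(sig) != m * m)
        stop("corrupted matrix shape in model file", call. = FALSE)
      structure(list(n = as.integer(cell$n), mu = mu,
                     Sigma = matrix(sig, m, m, byrow = TRUE)),
                class = "gaussian_cell")
    }))
  structure(list(m = m, dt = ser$dt, cells = cells,
                 max_k = unlist(ser$max_k),
                 timing = ser$timing,
                 reference_phase = ser$reference_phase,
                 flags = as.character(ser$flags), meta = ser$meta),
            class = "gait_model")
}
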