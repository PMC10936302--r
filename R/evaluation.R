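#' Ground-truth intent label from treadmill speed
#'
#' The literal speed rule of the treadmill experiment: a frame's ground
#' truth is `"SU"` when the belt runs faster than baseline, `"SD"` when
#' slower, `"NC"` when equal (within `tolerance`). Note that under this
#' rule the return ramp of a speed-up trial is still labeled `"SU"` until
#' the belt regains baseline, even though the walker is already slowing.
#'
#' @param speed belt speed(s), m/s.
#' @param baseline baseline speed, m/s.
#' @param tolerance half-width of the `"NC"` band, m/s (default 0: the
#'   literal rule).
#' @return character vector of labels.
#' @export
ground_truth <- function(speed, baseline = 1.4, tolerance = 0) {
  ifelse(speed > baseline + tolerance, "SU",
         ifelse(speed < baseline - tolerance, "SD", "NC"))
}

INTENT_LEVELS <- c("SU", "SD", "NC")
CLASS_LETTER <- c(SU = "U", SD = "D", NC = "N")

#' Per-timestep 3x3 confusion matrix
#'
#' Rows are ground truth, columns the classifier estimate, both over
#' (U, D, N) for speed-up, slow-down, no-change. Frame pairs where either
#' label is `NA` (standing or unresolved frames) are dropped.
#'
#' @param pred,truth equal-length character vectors of `"SU"`, `"SD"`,
#'   `"NC"` (or `NA`).
#' @return 3x3 integer matrix of class `confusion_matrix3` with dimnames
#'   `truth` and `pred` over `c("U", "D", "N")`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  keep <- !is.na(pred) & !is.na(truth)
  pred <- factor(CLASS_LETTER[pred[keep]], levels = c("U", "D", "N"))
  truth <- factor(CLASS_LETTER[truth[keep]], levels = c("U", "D", "N"))
  cm <- table(truth = truth, pred = pred)
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(truth = c("U", "D", "N"),
                               pred = c("U", "D", "N")))
  class(cm) <- c("confusion_matrix3", class(cm))
  cm
}

#' One-vs-rest counts for one class
#'
#' @param cm a [confusion()] matrix.
#' @param class `"U"`, `"D"`, or `"N"` (intent labels `"SU"` etc. also
#'   accepted).
#' @return named vector with `TP`, `TN`, `FP`, `FN`.
#' @export
class_counts <- function(cm, class) {
  if (class %in% names(CLASS_LETTER)) class <- CLASS_LETTER[[class]]
  stopifnot(class %in% rownames(cm))
  tp <- cm[class, class]
  fp <- sum(cm[, class]) - tp
  fn <- sum(cm[class, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Per-class precision, recall, F1, accuracy, and macro F1
#'
#' One-vs-rest metrics per class: precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)`, their harmonic mean F1, and per-class accuracy
#' `(TP + TN) / total`. Ratios with zero denominator are reported as 0 and
#' flagged in the `undefined` column. Macro F1 is the unweighted mean of
#' the three class F1 scores.
#'
#' @param cm a [confusion()] matrix.
#' @return list with `per_class` (data frame, one row per class) and
#'   `macro_f1`.
#' @export
class_metrics <- function(cm) {
  rows <- lapply(c("U", "D", "N"), function(cl) {
    ct <- class_counts(cm, cl)
    safe <- function(num, den) if (den == 0) 0 else num / den
    precision <- safe(ct[["TP"]], ct[["TP"]] + ct[["FP"]])
    recall <- safe(ct[["TP"]], ct[["TP"]] + ct[["FN"]])
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    total <- sum(ct)
    data.frame(class = cl, TP = ct[["TP"]], TN = ct[["TN"]],
               FP = ct[["FP"]], FN = ct[["FN"]],
               precision = precision, recall = recall, f1 = f1,
               accuracy = if (total == 0) 0 else
                 (ct[["TP"]] + ct[["TN"]]) / total,
               undefined = (ct[["TP"]] + ct[["FP"]] == 0) ||
                 (ct[["TP"]] + ct[["FN"]] == 0))
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, macro_f1 = mean(per_class$f1))
}

#' Per-trial detection delays
#'
#' Delay runs from the instant the belt first leaves baseline (trial onset)
#' to the first frame at or after onset whose predicted label matches the
#' trial's type, searched until the belt regains baseline. Trials never
#' correctly identified get `NA` and are excluded from delay averages (the
#' number of such misses should be reported alongside any mean).
#'
#' @param output an [run_intent()] output (columns `time`, `label`).
#' @param trials trial table from [protocol_trials()].
#' @return data frame with one row per trial: `trial`, `type`, `magnitude`,
#'   `onset`, `first_correct` (s or `NA`), `delay` (s or `NA`).
#' @export
time_delays <- function(output, trials) {
  if (is.null(trials) || nrow(trials) == 0L)
    stop("no trials to evaluate", call. = FALSE)
  if (any(trials$onset[-1L] < trials$end[-nrow(trials)]))
    stop("overlapping trial windows", call. = FALSE)
  res <- trials[, c("trial", "type", "magnitude", "onset")]
  res$first_correct <- NA_real_
  res$delay <- NA_real_
  for (i in seq_len(nrow(trials))) {
    win <- output$time >= trials$onset[i] & output$time <= trials$end[i]
    hit <- win & !is.na(output$label) & output$label == trials$type[i]
    if (any(hit)) {
      t0 <- min(output$time[hit])
      res$first_correct[i] <- t0
      res$delay[i] <- t0 - trials$onset[i]
    }
  }
  res
}

#' Threshold trade-off sweep
#'
#' Re-runs classification and evaluation at each squared-distance threshold
#' and tabulates the two quantities whose tension drives the threshold
#' choice: `1 - macro F1` (which favors high thresholds) and the mean
#' detection delay (which favors low ones), plus the flagged-frame count.
#'
#' @param stream a `gait_stream` over a perturbation protocol.
#' @param model a `gait_model`.
#' @param thresholds positive, sorted squared-distance thresholds.
#' @param config base [classifier_config()]; its threshold is replaced.
#' @param trials trial table from [protocol_trials()].
#' @param truth optional ground-truth labels (defaults to
#'   [ground_truth()] on the stream's `speed` column).
#' @param segmentation optional precomputed segmentation, reused across
#'   thresholds.
#' @return data frame with `threshold`, `one_minus_macro_f1`, `mean_delay`,
#'   `n_missed`, `flagged_frames`.
#' @export
threshold_sweep <- function(stream, model, thresholds,
                            config = classifier_config(), trials = NULL,
                            truth = NULL, segmentation = NULL) {
  if (any(thresholds <= 0) || is.unsorted(thresholds))
    stop("`thresholds` must be positive and sorted", call. = FALSE)
  if (is.null(truth)) truth <- ground_truth(stream$speed)
  if (is.null(segmentation)) segmentation <- segment_stream(stream,
                                                            causal = TRUE)
  rows <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$squared_md_threshold <- th
    out <- run_intent(stream, model, cfg, segmentation = segmentation)
    mf1 <- class_metrics(confusion(out$label, truth))$macro_f1
    flagged <- sum(!is.na(out$trigger) & out$trigger != "none")
    md <- NA_real_; missed <- NA_integer_
    if (!is.null(trials)) {
      del <- time_delays(out, trials)
      md <- mean(del$delay, na.rm = TRUE)
      missed <- sum(is.na(del$delay))
    }
    data.frame(threshold = th, one_minus_macro_f1 = 1 - mf1,
               mean_delay = md, n_missed = missed,
               flagged_frames = flagged)
  })
  do.call(rbind, rows)
}

#' Outlier removal by the 5 x IQR rule
#'
#' Drops values farther than `k` interquartile ranges from the median.
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7), so the rule is reproducible exactly.
#'
#' @param x numeric vector.
#' @param k multiplier on the IQR (default 5).
#' @return list with `kept`, `n_outliers`, `frac_outliers`.
#' @export
iqr_trim <- function(x, k = 5) {
  x <- x[!is.na(x)]
  med <- stats::median(x)
  iqr <- stats::IQR(x, type = 7)
  keep <- x >= med - k * iqr & x <= med + k * iqr
  list(kept = x[keep], n_outliers = sum(!keep),
       frac_outliers = if (length(x)) sum(!keep) / length(x) else 0)
}

#' Model-convergence curve
#'
#' Refits the gait model on growing prefixes of a constant-speed training
#' stream and scores the *full* stream with the real-time pipeline
#' (including the low-pass filter) against each prefix model. After
#' removing values beyond five interquartile ranges from the median, the
#' mean filtered squared distance is returned per training duration. As the
#' model converges this mean approaches the channel count — the mean of the
#' chi-squared distribution the squared distances follow.
#'
#' @param stream a constant-speed `gait_stream`.
#' @param durations training durations, s (each at most the stream length).
#' @param config a [classifier_config()].
#' @param iqr_k outlier multiplier (default 5).
#' @return data frame with `duration`, `mean_md2`, `n_outliers`,
#'   `frac_outliers`.
#' @export
convergence_curve <- function(stream, durations,
                              config = classifier_config(), iqr_k = 5) {
  dt <- attr(stream, "dt")
  if (is.null(dt)) dt <- stats::median(diff(stream$time))
  total <- nrow(stream) * dt
  if (any(durations > total + 1e-9))
    stop("requested duration exceeds the training stream", call. = FALSE)
  seg <- segment_stream(stream, causal = TRUE)
  rows <- lapply(durations, function(d) {
    n <- max(1L, floor(d / dt))
    idx <- seq_len(min(n, nrow(stream)))
    model <- tryCatch(
      fit_gait_model(stream_measurements(stream)[idx, , drop = FALSE],
                     segmentation = seg[idx, ], dt = dt,
                     reference_phase = config$reference_phase),
      error = function(e)
        stop("training duration ", d, " s is too short: ",
             conditionMessage(e), call. = FALSE))
    out <- run_intent(stream, model, config, segmentation = seg)
    tr <- iqr_trim(out$filtered[!is.na(out$filtered)], k = iqr_k)
    data.frame(duration = d, mean_md2 = mean(tr$kept),
               n_outliers = tr$n_outliers,
               frac_outliers = tr$frac_outliers)
  })
  do.call(rbind, rows)
}

#' Linear fits of mean squared distance versus speed offset
#'
#' Ordinary least-squares fits of the mean squared Mahalanobis distance
#' against the speed offset from baseline, fitted separately for negative
#' and positive offsets; the zero-offset point belongs to both fits. A
#' strong linear trend on each side supports reading the distance magnitude
#' as a proxy for the size of the intended speed change.
#'
#' @param dv numeric speed offsets from baseline, m/s.
#' @param mean_md2 mean squared distance at each offset.
#' @return list with `negative` and `positive` fits (each `slope`,
#'   `intercept`, `r_squared`, `n`, or `NULL` with a flag when a side has
#'   fewer than 2 points) and `flags`.
#' @export
md_speed_regression <- function(dv, mean_md2) {
  stopifnot(length(dv) == length(mean_md2))
  fit_side <- function(sel) {
    if (sum(sel) < 2L) return(NULL)
    f <- stats::lm(y ~ x, data = data.frame(x = dv[sel], y = mean_md2[sel]))
    rss <- sum(stats::residuals(f)^2)
    tss <- sum((mean_md2[sel] - mean(mean_md2[sel]))^2)
    list(slope = unname(stats::coef(f)[2L]),
         intercept = unname(stats::coef(f)[1L]),
         r_squared = if (tss == 0) 1 else 1 - rss / tss,
         n = sum(sel))
  }
  neg <- fit_side(dv <= 0)
  pos <- fit_side(dv >= 0)
  flags <- character(0)
  if (is.null(neg)) flags <- c(flags, "fewer than 2 non-positive offsets")
  if (is.null(pos)) flags <- c(flags, "fewer than 2 non-negative offsets")
  list(negative = neg, positive = pos, flags = flags)
}
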