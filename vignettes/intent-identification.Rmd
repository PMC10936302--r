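---
title: "Identifying walking-speed intent from cyclostationary gait models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying walking-speed intent from cyclostationary gait models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Assistive devices that support walking — exoskeletons, powered orthoses,
prostheses — need to know when their user wants to speed up (SU), slow down
(SD), or keep pace (NC). Pattern-recognition classifiers can do this but
typically demand hours of training data, which is impractical in settings
like physical therapy where a device may change users every hour. The
approach implemented here buys data efficiency with a strong structural
assumption: **at constant intended speed, walking is cyclostationary**.
Whatever the sensors measure at a given point of the gait cycle should look
statistically the same every time the cycle returns to that point.

`gaitintent` implements the full pipeline: a per-(phase, timestep) Gaussian
gait model with recursive training, Mahalanobis-distance novelty detection
with a chi-squared-calibrated threshold, phase-timing mismatch flags, and
cycle-speed-based typing of detected changes — plus a synthetic treadmill
gait generator and the evaluation machinery used to characterize the
algorithm.

## The model

The gait cycle is divided into four phases: left double support (LDS, both
feet down, left leg leading), left single support (LSS), right double
support (RDS), and right single support (RSS), visited cyclically in that
order. Within each phase, time is discretized into steps of `dt` (0.01 s at
the nominal 100 Hz). The measurement vector `x` (by default four joint
flexion angles, in degrees) at timestep `k` of phase `phi` is modeled as

    x | (phi, k)  ~  N(mu[phi,k], Sigma[phi,k])

with every (phase, timestep) cell independent of every other. Dropping the
temporal correlation between cells is exactly what makes the model cheap:
each cell only needs enough revisits of its own slot, and five minutes of
walking at ~1 s per cycle revisits every slot ~300 times.

Cells are trained with single-pass recursive updates (`update_cell()`)
that reproduce the batch maximum-likelihood estimates exactly: the sample
mean, and the divide-by-`n` covariance. The divide-by-`n` (rather than
`n - 1`) form is used deliberately — it is the maximum-likelihood Gaussian
fit, and at ~300 observations per cell the distinction is immaterial. The
equivalence with batch estimation is enforced by a property test across
1,000 random streams at tolerance 1e-10.

## Scoring and calibration

An incoming frame is scored against its cell with the squared Mahalanobis
distance `d2 = (x - mu)' (Sigma + ridge I)^{-1} (x - mu)`, computed via a
Cholesky solve. For Gaussian in-model data, `d2` follows a chi-squared
distribution with `m` degrees of freedom (`m` = number of channels), which
gives the threshold a probabilistic meaning: with `m = 4`, a squared
distance of 13.5 sits at CDF 0.9909, so under constant intent roughly 1% of
raw frames exceed it. The raw `d2` signal is noisy, so it passes through a
causal first-order Butterworth low-pass filter (cutoff 1.2 Hz, bilinear
discretization via the `signal` package) before the threshold test; the
filter state is initialized at the first raw value so there is no startup
transient to cause a spurious trigger.

Two timing questions complement the distance test, because a change of
intended speed also distorts gait timing:

* **Question A** — the current phase has already lasted longer than the
  model's timestep count for that phase by more than
  `timing_std_multiplier` training standard deviations. (Beyond the model's
  range there is no cell to score against; the filter is held frozen and
  only this flag can trigger.)
* **Question B** — the phase that just ended finished short of the model's
  count by more than the same margin. The flag is held until the current
  phase ends; the persistence scope is a design choice of this package.
* **Question C** — independent of any flag, the classifier tracks whether
  the most recently completed gait cycle was faster or slower than the
  training mean. When any trigger is active, that direction types the label:
  faster gives SU, slower gives SD. A trigger with no completed cycle, or a
  cycle that exactly matched the mean, yields NC with a `type_unresolved`
  diagnostic — a degenerate case the design resolves conservatively.

Labels are per-frame and non-latching: a change label is emitted while a
trigger is active and reverts to NC otherwise, which is what per-timestep
confusion-matrix scoring expects.

## Phase segmentation

When foot-contact flags are available they are used directly: one foot down
gives that leg's single support; both down give the double support of the
leading leg, operationalized as *the leg that entered stance most recently*
(a heel strike is what opens a double support). Without contacts, phases
are inferred from leg kinematics through the **virtual leg vector**
`2 (knee - hip) + (heel - knee)`. Its angle with the vertical falls
monotonically through stance and rises through swing. Two details matter:

* The *unsigned* angle with the vertical folds at the vertical crossing,
  so trend detection uses the sagittal *signed* angle (sign taken from the
  component along the progression axis).
* Trend detection smooths with a 5-frame causal moving average and requires
  a reversal to persist 3 frames. In batch mode the switch is backdated to
  the raw-series extremum inside the detection window, which places
  transitions on the true turning points; for streaming use
  (`causal = TRUE`, the default inside `run_intent()`) the state switches
  only at the confirmation frame and already-emitted frames are never
  relabeled. This keeps the classifier strictly causal — verified by a
  truncation-equivalence test — at the cost of a few frames of transition
  latency in the kinematic path.

The timestep `k` starts at 1 on the first frame of a phase and increments
once per frame; off-grid event times are binned to the nearest `dt` cell.

## The synthetic generator

The generator exists to produce data with exactly the statistical structure
the algorithm assumes, under the treadmill protocol of the experiment it
mimics, with known ground truth. A `gait_template` holds per-channel
low-order Fourier series over the normalized cycle phase; the default is a
four-channel hip/knee flexion pattern whose coefficients were calibrated
once so that the virtual-leg angle of the implied planar two-link leg peaks
at heel strike and bottoms out at toe-off, with hip flexion spanning about
-11 to 24 degrees and knee flexion 0 to 60 degrees. Defaults, each chosen
as a realistic value and then left alone:

* `cycle_duration_at_reference = 1.03` s at 1.4 m/s — the baseline is the
  average preferred walking speed of healthy adults, and ~1 s cycles are
  typical there. Cycle duration follows the power law
  `T(v) = 1.03 * (1.4 / v)^0.5`: walking faster shortens the cycle, with
  the square-root exponent reflecting that cadence and stride length share
  the speed increase roughly equally.
* `amplitude_speed_gain = 0.3` per (m/s): joint excursions grow ~3% per
  0.1 m/s of speed, a moderate kinematic response.
* `phase_fractions = (0.12, 0.38, 0.12, 0.38)` for (LDS, LSS, RDS, RSS) —
  a typical ~24% double-support share.
* Measurement noise: independent 1-degree-sd Gaussian per channel
  (configurable as a full covariance).
* Treadmill ramps at 0.5 m/s^2, a mild everyday-pedestrian acceleration;
  the protocol dwells 15 s at each plateau, with trials ordered
  small/small/small, medium x3, large x3, speed-ups before slow-downs.

What the generator deliberately does **not** emulate: stride-to-stride
timing jitter at constant speed (its timing is deterministic given the
speed trace), slow drift of baseline gait, inter-subject variability,
asymmetries, soft-tissue and sensor artifacts, and any true flight phase.
Consequences worth being explicit about: with deterministic timing the
trained timing standard deviations are 0, so Questions A and B flag on a
single-timestep mismatch — on this data they are maximally sensitive, and
real, jittery data would need the `timing_std_multiplier` margin to do real
work. Passing the synthetic suite therefore demonstrates the algorithm's
internal correctness and calibration, not human-subject performance.

## Numerical choices

* Covariance ridge `1e-6` degrees^2 keeps low-count or noise-free cells
  invertible; it is ~12 orders below the degree-scale variances it guards.
* The generator snaps its cycle-phase accumulator to phase boundaries
  within 1e-9: when a boundary falls exactly on a sample (a 1.03 s cycle is
  exactly 103 frames), accumulated rounding must not flip frames across it
  and fabricate timing variability.
* Trend detection ignores smoothed-series differences below
  `1e-10 * (1 + max |angle|)` — rounding dust is not a trend.
* Quartiles for the 5 x IQR outlier rule use linear interpolation between
  order statistics (`quantile` type 7), making the rule bit-reproducible.
* Ties in Question C (`duration == cycle_mean` exactly, reachable because
  durations are integer multiples of `dt`) give direction "unchanged",
  which blocks typing rather than guessing.
* Model files are JSON with row-major matrices and a version tag; reloaded
  cells resume recursive training exactly. Timing statistics are batch
  quantities recomputed at fit time.

## Evaluation machinery

`ground_truth()` applies the literal belt-speed rule (faster / equal /
slower than baseline maps to SU / NC / SD). Note one documented quirk this
inherits: during the return ramp of a speed-up trial the belt is still
above baseline, so frames are labeled SU even though the walker is already
slowing; the rule is kept literal for comparability. `confusion()`,
`class_counts()`, and `class_metrics()` implement per-timestep one-vs-rest
scoring with macro-averaged F1; 0/0 ratios are reported as 0 and flagged.
`time_delays()` measures onset-to-first-correct-label per trial, with
never-correct trials excluded from averages but counted. `threshold_sweep()`
exposes the delay-versus-F1 trade-off; `convergence_curve()` refits on
growing training prefixes and tracks the outlier-trimmed mean filtered
squared distance, which approaches the channel count as the model
converges; `md_speed_regression()` fits the mean distance against the speed
offset separately per side of baseline.

## Problem sizes

The shipped tests and the acceptance script use a 300 s constant-speed
training stream (~290 cycles, matching the five-minute training session the
protocol is built around), a full 18-trial protocol stream (~570 s), 60 s
streams per constant-speed condition for the distance-versus-offset
regression, and 120 s of fresh data for the chi-squared mean-recovery
check. These sizes put every Monte-Carlo estimate well inside the stated
tolerances while keeping a full run under a minute.

## A worked run

```{r}
library(gaitintent)

template <- default_gait_template()
train <- simulate_gait(template, 1.4, duration = 300, seed = 11)
model <- fit_gait_model(train)
model

protocol <- build_standard_protocol()
stream <- simulate_gait(template, protocol, seed = 12)
out <- run_intent(stream, model)

met <- class_metrics(confusion(out$label, ground_truth(stream$speed)))
met$macro_f1
time_delays(out, protocol_trials(protocol))
```

## Known limitations

* The deterministic synthetic timing makes timing flags hair-triggered (see
  above); on real data their sensitivity is governed by the actual timing
  variance.
* Re-baselining for slow drift of a user's gait is out of scope, as is any
  device control response; the classifier only emits labels.
* The kinematic segmentation path assumes planar sagittal motion with a
  known progression axis.
* With belt speed 0 the model is silent by design: standing frames carry a
  distinct label and are excluded from training and classification.
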