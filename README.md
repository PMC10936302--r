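# gaitintent

Real-time identification of a walker's intent to **speed up (SU)**, **slow
down (SD)**, or **make no change (NC)**, from multichannel kinematic time
series — with minutes, not hours, of training data. The intended users are
researchers and engineers working on assistive devices (exoskeletons,
powered orthoses, prostheses) who need a sensor-agnostic, data-efficient
intent signal and a reproducible way to evaluate it.

## The idea

At constant intended speed, walking is treated as a **cyclostationary
process**: the gait cycle is split into four phases — left/right double
support, left/right single support (LDS, LSS, RDS, RSS) — and each phase
into 0.01 s timesteps. The measurement vector *x* (by default four joint
flexion angles, in degrees) at timestep *k* of phase *φ* is modeled as

> *x* | (*φ*, *k*) ~ N(*μ*<sub>*φ*,*k*</sub>, *Σ*<sub>*φ*,*k*</sub>),

with every (phase, timestep) cell independent of the others. That
independence assumption is what makes the model data-efficient: each cell's
mean and maximum-likelihood covariance is estimated recursively from ~300
revisits in five minutes of constant-speed walking.

At run time each frame is scored by its squared Mahalanobis distance

> *d*² = (*x* − *μ*)ᵀ (*Σ* + λI)⁻¹ (*x* − *μ*),

low-pass filtered (first-order Butterworth, 1.2 Hz), and compared to a
threshold calibrated through the χ² distribution that *d*² follows for
in-model data: with 4 channels, the default threshold 13.5 sits at
χ²₄ CDF 0.99. Phase-timing mismatches — a phase outlasting the model
(Question A) or ending short of it (Question B) — also trigger, covering
frames where no Gaussian cell exists. A trigger is typed by the duration of
the most recently completed gait cycle (Question C): faster than the
training mean ⇒ SU, slower ⇒ SD.

The package also provides gait-phase segmentation (from foot contacts or
from the virtual-leg vector 2·(knee − hip) + (heel − knee)), a synthetic
treadmill-protocol gait generator with known ground truth, and the full
evaluation suite: per-timestep 3×3 confusion matrices, one-vs-rest
precision/recall/F1/accuracy, per-trial detection delays, threshold
trade-off sweeps, model-convergence curves with 5×IQR outlier trimming,
and distance-versus-speed-offset regression.

## Worked example

```r
library(gaitintent)

template <- default_gait_template()

# 5 minutes of constant-speed walking at 1.4 m/s trains the model
train <- simulate_gait(template, 1.4, duration = 300, seed = 11)
model <- fit_gait_model(train)
model
#> Cyclostationary gait model: 4 channels at dt = 0.01 s
#>   timesteps per phase: LDS=13, LSS=39, RDS=12, RSS=39
#>   cycle duration 1.030 +/- 0.000 s over 290 training cycles

# the 18-trial treadmill protocol tests it
protocol <- build_standard_protocol()
stream <- simulate_gait(template, protocol, seed = 12)
out <- run_intent(stream, model)

confusion(out$label, ground_truth(stream$speed))
#>      pred
#> truth     U    D     N
#>     U 12348    0  1870
#>     D     0 9877  4572
#>     N   324  165 28018
class_metrics(confusion(out$label, ground_truth(stream$speed)))$macro_f1
#> [1] 0.8716389

delays <- time_delays(out, protocol_trials(protocol))
aggregate(delay ~ type + magnitude, delays, median)
#>   type magnitude delay
#> 1   SD       0.1  0.80
#> 2   SU       0.1  0.60
#> 3   SD       0.2  0.76
#> 4   SU       0.2  0.59
#> 5   SD       0.3  0.84
#> 6   SU       0.3  0.86
```

The model's 103 timesteps reproduce the 1.03 s gait cycle at 100 Hz. On
the synthetic protocol the classifier reaches a macro F1 of 0.87 per
timestep, and every trial magnitude is correctly typed in well under one
gait cycle (medians 0.59–0.86 s). Misclassifications concentrate where the
ground-truth rule is literal about belt speed: during return ramps the belt
is still off-baseline while the gait is already normalizing.

A command-line front end over the same functions lives at
`inst/cli/gaitintent.R` with `simulate`, `train`, `run`, `evaluate`,
`sweep`, and `converge` subcommands.

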