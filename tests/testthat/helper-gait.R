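# Shared fixtures, memoized so expensive simulations run at most once per
# test session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_template <- function() fixture("template", function() default_gait_template())

# 300 s of constant-speed training data at the reference speed (the study's
# 5-minute training set) and the model fitted on it
fx_train <- function() fixture("train", function()
  simulate_gait(fx_template(), 1.4, duration = 300, seed = 101))

fx_model <- function() fixture("model", function() fit_gait_model(fx_train()))

# full 18-trial treadmill protocol and the classifier output over it
fx_protocol <- function() fixture("protocol", function() build_standard_protocol())

fx_protocol_stream <- function() fixture("protocol_stream", function()
  simulate_gait(fx_template(), fx_protocol(), seed = 202))

fx_protocol_seg <- function() fixture("protocol_seg", function()
  segment_stream(fx_protocol_stream(), causal = TRUE))

fx_protocol_out <- function() fixture("protocol_out", function()
  run_intent(fx_protocol_stream(), fx_model(),
             segmentation = fx_protocol_seg()))
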