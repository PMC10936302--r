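test_that("standard protocol has the fixed trial structure", {
  prof <- build_standard_protocol(baseline_speed = 1.4,
                                  deltas = c(0.1, 0.2, 0.3),
                                  dwell = 15, acceleration = 0.5)
  tr <- protocol_trials(prof)
  expect_equal(nrow(tr), 18L)
  expect_equal(sum(tr$type == "SU"), 9L)
  expect_equal(sum(tr$type == "SD"), 9L)
  # fixed order: three small, three medium, three large, SU block then SD
  expect_equal(tr$magnitude, rep(rep(c(0.1, 0.2, 0.3), each = 3), 2))
  expect_equal(tr$type, rep(c("SU", "SD"), each = 9))
  # target speeds: 9 above and 9 below baseline
  targets <- speed_at(prof, (tr$plateau_start + tr$plateau_end) / 2)
  expect_equal(sum(targets > 1.4), 9L)
  expect_equal(sum(targets < 1.4), 9L)
  # total duration is the exact sum of the piecewise segments
  ramps <- 2 * sum(tr$magnitude) / 0.5
  expect_equal(profile_duration(prof),
               1.4 / 0.5 + 19 * 15 + 18 * 15 + ramps)
})

test_that("single-trial plateau and ramp have exact durations", {
  a <- 0.5
  prof <- build_standard_protocol(deltas = 0.3, dwell = 15,
                                  acceleration = a, reps = 1L)
  tr <- protocol_trials(prof)
  expect_equal(nrow(tr), 2L)                       # one SU + one SD
  expect_equal(tr$plateau_end[1] - tr$plateau_start[1], 15)
  expect_equal(tr$plateau_start[1] - tr$onset[1], 0.3 / a)
  expect_equal(speed_at(prof, tr$plateau_start[1] + 1), 1.7)
})

test_that("empty protocol is a ramp to baseline then constant", {
  prof <- build_standard_protocol(deltas = numeric(0))
  expect_null(protocol_trials(prof))
  t <- seq(1.4 / 0.5, profile_duration(prof) + 50, by = 0.5)
  expect_true(all(speed_at(prof, t) == 1.4))
})

test_that("invalid protocol arguments error", {
  expect_error(build_standard_protocol(dwell = 0), "dwell")
  expect_error(build_standard_protocol(acceleration = -1), "acceleration")
  expect_error(build_standard_protocol(baseline_speed = 0), "baseline")
  expect_error(treadmill_profile(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(treadmill_profile(c(0, 1), c(1, -1)), ">= 0")
})

test_that("noiseless constant-speed stream is exactly periodic at 1.03 s", {
  tpl <- default_gait_template(noise_sd = 1e-12)
  st <- simulate_gait(tpl, 1.4, duration = 10, seed = 1)
  meas <- stream_measurements(st)
  # cycle duration at reference speed is 103 frames of 0.01 s
  period <- round(tpl$cycle_duration_at_reference / 0.01)
  expect_equal(period, 103L)
  expect_equal(meas[1:500, ], meas[1:500 + period, ], tolerance = 1e-6)
  expect_equal(st$phase[1:500], st$phase[1:500 + period])
})

test_that("training-speed cycle duration matches the 1.03 s calibration", {
  model <- fx_model()
  expect_equal(model$timing$cycle_mean, 1.03, tolerance = 1e-6)
})

test_that("seeding contract: same seed reproduces, different seed varies noise only", {
  tpl <- fx_template()
  a <- simulate_gait(tpl, 1.4, duration = 5, seed = 7)
  b <- simulate_gait(tpl, 1.4, duration = 5, seed = 7)
  c <- simulate_gait(tpl, 1.4, duration = 5, seed = 8)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(stream_measurements(a),
                                stream_measurements(c))))
  expect_identical(a$phase, c$phase)
})

test_that("zero belt speed yields standing frames with no phase advance", {
  tpl <- fx_template()
  prof <- treadmill_profile(c(0, 1, 1.001, 5), c(0, 0, 1.4, 1.4))
  st <- simulate_gait(tpl, prof, seed = 2)
  stand <- st$speed <= 0
  expect_true(all(st$phase[stand] == "stand"))
  expect_true(all(st$cycle_s[stand] == st$cycle_s[which(stand)[1]]))
  expect_true(all(st$phase[!stand] %in% c(GAIT_PHASES)))
})

test_that("speed offset increases both trajectory displacement and cycle-duration offset", {
  tpl <- fx_template()
  s <- seq(0, 1, length.out = 50)
  base <- evaluate_template(tpl, s, 1.4)
  disp <- sapply(c(1.5, 1.6, 1.7), function(v)
    mean(abs(evaluate_template(tpl, s, v) - base)))
  expect_true(all(diff(disp) > 0))
  Tv <- function(v) tpl$cycle_duration_at_reference * (1.4 / v)^tpl$cycle_speed_exponent
  offs <- abs(sapply(c(1.5, 1.6, 1.7), Tv) - Tv(1.4))
  expect_true(all(diff(offs) > 0))
  # slower speeds lengthen the cycle
  expect_gt(Tv(1.1), Tv(1.4))
})

test_that("per-cell samples at constant speed are i.i.d. draws around the template", {
  # generator contract: empirical cell means approach the template value
  model <- fx_model()
  tpl <- fx_template()
  # LSS spans cycle phases [0.12, 0.5); its k-th cell sits k steps in
  cell <- model$cells$LSS[[20L]]
  # LSS begins at frame 13 of the 103-frame cycle; its k-th cell is k - 1
  # frames later
  s_cell <- (13 + 19) / 103
  expect_lt(max(abs(cell$mu - evaluate_template(tpl, s_cell)[1, ])), 0.25)
  # covariance approaches the 1-degree-sd diagonal noise
  expect_lt(max(abs(cell$Sigma - diag(1, 4))), 0.35)
})

test_that("forward kinematics place the leg segments consistently", {
  tpl <- fx_template()
  mk_stream <- function(hip, knee) {
    st <- data.frame(time = c(0, 0.01),
                     hip_l = hip, knee_l = knee, hip_r = 0, knee_r = 0)
    st$phase <- "LSS"; st$speed <- 0
    attr(st, "dt") <- 0.01
    attr(st, "channels") <- c("hip_l", "knee_l", "hip_r", "knee_r")
    class(st) <- c("gait_stream", "data.frame")
    derive_segment_positions(st, tpl, thigh_length = 0.5,
                             shank_length = 0.5, hip_height = 1)
  }
  # straight vertical leg: hip, knee, heel collinear and vertical
  p <- mk_stream(0, 0)
  expect_equal(p$knee_l_x[1], p$hip_l_x[1])
  expect_equal(p$heel_l_x[1], p$hip_l_x[1])
  expect_equal(p$heel_l_z[1], p$hip_l_z[1] - 1)
  # hip flexed 90 with a straight knee: whole leg horizontal
  p <- mk_stream(90, 0)
  expect_equal(p$knee_l_z[1], p$hip_l_z[1])
  expect_equal(p$heel_l_x[1], p$knee_l_x[1] + 0.5)
  expect_equal(p$heel_l_z[1], p$knee_l_z[1])
  # hip 90, knee 90: shank vertical, heel directly below the knee
  p <- mk_stream(90, 90)
  expect_equal(p$heel_l_x[1], p$knee_l_x[1])
  expect_equal(p$heel_l_z[1], p$knee_l_z[1] - 0.5)
  # missing roles error
  tpl2 <- fx_template(); tpl2$roles <- NULL
  expect_error(derive_segment_positions(mk_stream(0, 0), tpl2), "roles")
})

test_that("stream CSV round-trips", {
  st <- simulate_gait(fx_template(), 1.4, duration = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_gait_stream(st, path)
  st2 <- read_gait_stream(path)
  expect_equal(stream_measurements(st2), stream_measurements(st),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_identical(st2$phase, st$phase)
  expect_equal(attr(st2, "channels"), attr(st, "channels"))
})

test_that("template validation rejects broken invariants", {
  coef <- matrix(rnorm(12), 4)
  expect_error(gait_template(coef, phase_fractions = c(0.3, 0.3, 0.3, 0.2)),
               "sum to 1")
  expect_error(gait_template(coef, phase_fractions = c(0.5, 0.5, 0.1, -0.1)),
               "positive")
  expect_error(gait_template(coef, noise_covariance = diag(c(1, 1, 1, 0))),
               "positive definite")
  expect_error(gait_template(coef, cycle_duration_at_reference = 0), "> 0")
})
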