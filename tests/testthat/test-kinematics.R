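# Preprocessing, cycle segmentation and feature extraction.

test_that("velocity of a constant trace is identically zero", {
  prep <- preprocess(rep(2.5, 120), smoothing_window = 0.1,
                     sampling_rate = 60)
  expect_equal(prep$velocity, rep(0, 120), tolerance = 1e-12)
})

test_that("velocity of a sinusoid matches the closed-form derivative", {
  # d(t) = (A/2)(1 - cos 2 pi f t)  =>  max d' = pi A f; the raw discrete
  # maximum needs a fine grid (the peak falls mid-sample at 60 Hz, where
  # the sub-sample refinement inside per_cycle_metrics takes over)
  sig <- simulate_signal(clean_spec(sampling_rate = 100), seed = 1)
  prep <- preprocess(sig, smoothing_window = 0)
  expect_equal(max(prep$velocity), pi * 1 * 2, tolerance = 0.01)
})

test_that("smoothing contracts the variance of white noise", {
  set.seed(5)
  x <- rnorm(600)
  prep <- preprocess(x, smoothing_window = 0.1, sampling_rate = 60)
  expect_lt(var(prep$displacement), var(x))
})

test_that("a sub-two-sample window leaves the trace unsmoothed with a warning", {
  set.seed(6)
  x <- rnorm(120)
  expect_warning(prep <- preprocess(x, smoothing_window = 0.01,
                                    sampling_rate = 60),
                 "unsmoothed")
  expect_equal(prep$displacement, x)
})

test_that("a clean 2 Hz trace segments into exactly 10 half-second cycles", {
  sig <- simulate_signal(clean_spec(), seed = 1)
  cyc <- segment_cycles(sig$displacement, 60)
  expect_equal(nrow(cyc), 10L)
  expect_true(all(abs(cyc$duration - 0.5) <= 1 / 60 + 1e-12))
  expect_equal(cyc$amplitude, rep(1, 10), tolerance = 1e-9)
})

test_that("constant and near-flat traces raise the insufficient-cycles condition", {
  expect_error(segment_cycles(rep(1, 300), 60),
               class = "kinemed_insufficient_cycles")
  expect_error(extract_features(
    structure(list(displacement = numeric(0), sampling_rate = 60,
                   task = "t", meta = list()), class = "movement_signal")),
    class = "kinemed_validation_error")
})

test_that("high-frequency ripple below the prominence floor is rejected", {
  sig <- simulate_signal(clean_spec(), seed = 1)
  t <- (seq_along(sig$displacement) - 1) / 60
  rippled <- sig$displacement + 0.05 * sin(2 * pi * 12 * t)
  cyc <- segment_cycles(rippled, 60, min_prominence_fraction = 0.2)
  expect_equal(nrow(cyc), 10L)
})

test_that("per-cycle speeds obey the sinusoid closed forms", {
  sig <- simulate_signal(clean_spec(sampling_rate = 100), seed = 1)
  prep <- preprocess(sig, smoothing_window = 0)
  cyc <- per_cycle_metrics(segment_cycles(prep$displacement, 100),
                           prep$velocity)
  expect_equal(mean(cyc$opening_speed), pi * 2, tolerance = 0.01)
  expect_equal(mean(cyc$closing_speed), pi * 2, tolerance = 0.01)
  expect_equal(mean(cyc$rms_velocity), pi * 2 / sqrt(2), tolerance = 0.01)
})

test_that("time reversal swaps opening and closing speeds", {
  sp <- clean_spec(opening_fraction = 0.35)
  sig <- simulate_signal(sp, seed = 1)
  fwd <- preprocess(sig, smoothing_window = 0)
  cyc_f <- per_cycle_metrics(segment_cycles(fwd$displacement, 60),
                             fwd$velocity)
  rev_prep <- preprocess(rev(sig$displacement), smoothing_window = 0,
                         sampling_rate = 60)
  cyc_r <- per_cycle_metrics(segment_cycles(rev_prep$displacement, 60),
                             rev_prep$velocity)
  expect_equal(sort(cyc_f$opening_speed), sort(cyc_r$closing_speed),
               tolerance = 1e-6)
  expect_equal(sort(cyc_f$closing_speed), sort(cyc_r$opening_speed),
               tolerance = 1e-6)
})

test_that("displacement scaling multiplies amplitude and speed features, leaves timing alone", {
  sig <- simulate_signal(signal_spec(duration = 8, noise_sd = 0), seed = 3)
  f1 <- extract_features(sig)
  sig3 <- sig
  sig3$displacement <- 3 * sig$displacement
  f3 <- extract_features(sig3)
  scale_feats <- c("mean_amplitude", "mean_speed", "mean_rms_velocity",
                   "mean_opening_speed", "mean_closing_speed",
                   "sd_amplitude", "sd_speed", "sd_rms_velocity",
                   "sd_opening_speed", "sd_closing_speed")
  invariant <- c("mean_cycle_duration", "frequency", "amplitude_decay",
                 "velocity_decay", "frequency_decay", "sd_cycle_duration",
                 "range_cycle_duration", "cv_amplitude", "cv_cycle_duration",
                 "cv_speed")
  expect_equal(f3[scale_feats], 3 * f1[scale_feats], tolerance = 1e-9)
  expect_equal(f3[invariant], f1[invariant], tolerance = 1e-9)
})

test_that("time dilation rescales rates, durations and speeds reciprocally", {
  sig <- simulate_signal(signal_spec(duration = 8, noise_sd = 0), seed = 4)
  slow <- sig
  slow$sampling_rate <- 60 / 1.5   # same samples played 1.5x slower
  f1 <- extract_features(sig, no_smooth())
  f2 <- extract_features(slow, no_smooth())
  expect_equal(f2[["frequency"]], f1[["frequency"]] / 1.5, tolerance = 1e-9)
  expect_equal(f2[["mean_cycle_duration"]],
               f1[["mean_cycle_duration"]] * 1.5, tolerance = 1e-9)
  expect_equal(f2[["mean_speed"]], f1[["mean_speed"]] / 1.5, tolerance = 1e-9)
  expect_equal(f2[["cv_cycle_duration"]], f1[["cv_cycle_duration"]],
               tolerance = 1e-9)
})

test_that("noiseless jitter-free features hit their exact values", {
  sig <- simulate_signal(clean_spec(), seed = 1)
  fv <- extract_features(sig, no_smooth())
  expect_equal(fv[["mean_amplitude"]], 1, tolerance = 1e-3)
  expect_equal(fv[["frequency"]], 2, tolerance = 1e-9)
  expect_equal(fv[["mean_cycle_duration"]], 0.5, tolerance = 1e-9)
  sds <- fv[c("sd_amplitude", "sd_speed", "sd_opening_speed",
              "sd_closing_speed", "sd_cycle_duration")]
  expect_true(all(sds < 1e-6))
  expect_true(all(abs(fv[c("amplitude_decay", "velocity_decay",
                           "frequency_decay")]) < 1e-6))
})

test_that("planted decays are recovered by the normalized OLS slope", {
  # amplitude and velocity decays are linear by construction: exact recovery
  for (rate in c(0.02, 0.05, 0.1)) {
    fa <- extract_features(
      simulate_signal(clean_spec(amplitude_decay_rate = rate), seed = 1),
      no_smooth())
    expect_lt(abs(fa[["amplitude_decay"]] + rate), 0.01)
    fv <- extract_features(
      simulate_signal(clean_spec(velocity_decay_rate = rate), seed = 1),
      no_smooth())
    expect_lt(abs(fv[["velocity_decay"]] + rate), 0.01)
  }
  # duration growth T_k = T0 (1 + r k) maps onto the rate regression
  # hyperbolically; oracle = closed-form OLS of 1/(1 + r k) on k
  rate <- 0.05
  sig <- simulate_signal(clean_spec(frequency_decay_rate = rate), seed = 1)
  k <- sig$cycles$cycle
  oracle_fit <- lm(I(1 / sig$cycles$duration) ~ k)
  oracle <- unname(coef(oracle_fit)[2] / coef(oracle_fit)[1])
  fv <- extract_features(sig, no_smooth())
  # durations are quantised to the sample grid, hence the small slack
  expect_lt(abs(fv[["frequency_decay"]] - oracle), 0.005)
  expect_lt(fv[["frequency_decay"]], -0.03)  # clearly negative
})

test_that("planted duration jitter is recovered in the duration CV", {
  sp <- clean_spec(duration = 100, duration_jitter_cv = 0.10)
  sig <- simulate_signal(sp, seed = 12)
  expect_gt(nrow(sig$cycles), 190)
  fv <- extract_features(sig, no_smooth())
  expect_gt(fv[["cv_cycle_duration"]], 0.08)
  expect_lt(fv[["cv_cycle_duration"]], 0.12)
})

test_that("extraction recovers the generative amplitude and frequency within 2%", {
  sp <- signal_spec(duration = 10, noise_sd = 0, amplitude_decay_rate = 0,
                    frequency_decay_rate = 0, amplitude_jitter_cv = 0,
                    duration_jitter_cv = 0)
  fv <- extract_features(simulate_signal(sp, seed = 2))  # default smoothing
  expect_equal(fv[["mean_amplitude"]], 1, tolerance = 0.02)
  expect_equal(fv[["frequency"]], 2, tolerance = 0.02)
})

test_that("CV definitions hold wherever means are nonzero", {
  sig <- simulate_signal(signal_spec(duration = 8), seed = 6)
  fv <- extract_features(sig)
  expect_equal(fv[["cv_amplitude"]],
               fv[["sd_amplitude"]] / fv[["mean_amplitude"]])
  expect_equal(fv[["cv_cycle_duration"]],
               fv[["sd_cycle_duration"]] / fv[["mean_cycle_duration"]])
  expect_equal(fv[["cv_speed"]], fv[["sd_speed"]] / fv[["mean_speed"]])
  expect_gte(fv[["range_cycle_duration"]], 0)
})
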