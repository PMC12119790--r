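# Shared fixtures, all built in code.

# A clean raised-cosine signal: with opening_fraction = 0.5 the trace is
# exactly d(t) = (A/2) * (1 - cos(2 pi f t)), the closed-form oracle case.
clean_spec <- function(sampling_rate = 60, duration = 5, A = 1, f = 2,
                       opening_fraction = 0.5,
                       amplitude_decay_rate = 0, velocity_decay_rate = 0,
                       frequency_decay_rate = 0, amplitude_jitter_cv = 0,
                       duration_jitter_cv = 0, noise_sd = 0) {
  signal_spec(sampling_rate = sampling_rate, duration = duration,
              base_amplitude = A, base_frequency = f,
              opening_fraction = opening_fraction,
              amplitude_decay_rate = amplitude_decay_rate,
              velocity_decay_rate = velocity_decay_rate,
              frequency_decay_rate = frequency_decay_rate,
              amplitude_jitter_cv = amplitude_jitter_cv,
              duration_jitter_cv = duration_jitter_cv,
              noise_sd = noise_sd)
}

no_smooth <- function() kin_config(smoothing_window = 0)

# Published per-task percentage changes and p-values for the twenty
# canonical features (hand opening / finger tapping), used as a printed-table
# input fixture for the effect-report rules.
published_effects <- function() {
  tab <- read.csv(text = '
feature,ho_pct,ho_p,ft_pct,ft_p
mean_amplitude,6.59,7.44e-05,4.01,0.0284
mean_speed,13.52,2.85e-13,16.06,1.49e-16
mean_rms_velocity,13.34,4.52e-15,14.87,2.74e-15
mean_opening_speed,14.48,3.14e-16,17.21,7.24e-18
mean_closing_speed,12.80,4.53e-09,13.20,4.66e-12
mean_cycle_duration,-52.23,0.327,1.37,0.979
frequency,10.03,2.42e-09,12.90,1.42e-16
amplitude_decay,-1.91,0.244,-3.21,0.027
velocity_decay,-3.43,0.0149,-5.04,9.88e-05
frequency_decay,-2.78,0.0346,-2.43,0.052
sd_amplitude,0.39,0.873,0.86,0.724
sd_speed,9.96,0.00012,3.67,0.123
sd_rms_velocity,7.78,0.0026,1.95,0.421
sd_opening_speed,10.16,2.80e-05,5.87,0.009
sd_closing_speed,11.26,3.16e-06,1.08,0.617
sd_cycle_duration,-15.78,6.13e-08,-25.58,1.08e-13
range_cycle_duration,-18.34,2.57e-04,-21.34,2.00e-06
cv_amplitude,-7.36,0.0142,-4.53,0.088
cv_cycle_duration,-6.99,0.0060,-10.24,0.00022
cv_speed,-5.62,0.0227,-8.63,0.00011
', stringsAsFactors = FALSE)
  list(
    hand_opening = data.frame(feature = tab$feature, pct_change = tab$ho_pct,
                              p_value = tab$ho_p, stringsAsFactors = FALSE),
    finger_tapping = data.frame(feature = tab$feature, pct_change = tab$ft_pct,
                                p_value = tab$ft_p, stringsAsFactors = FALSE)
  )
}

# Small feature table with a known additive condition effect and patient
# intercepts, for direct LMM checks without signal extraction.
toy_feature_table <- function(n_patients = 30, effect = 1, sigma = 0.5,
                              seed = 1) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_patients), function(p) {
    b <- rnorm(1, 0, 1)
    age <- round(runif(1, 45, 75))
    do.call(rbind, lapply(1:2, function(v) {
      data.frame(patient_id = sprintf("P%02d", p), visit_id = v,
                 task = "finger_tapping",
                 condition = c("OFF", "ON"),
                 age_at_visit = age + 0.5 * (v - 1),
                 mean_speed = 10 + b + c(0, effect) + rnorm(2, 0, sigma),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

# Jaccard index between a fitted component's nonzero support and its best
# matching planted block.
support_jaccard <- function(fit, component, blocks) {
  sup <- rownames(fit$loadings)[fit$loadings[, component] != 0]
  max(vapply(blocks, function(b) {
    length(intersect(sup, b)) / length(union(sup, b))
  }, numeric(1)))
}
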