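#' Specification of a synthetic movement signal
#'
#' Parameterises the generative model of one quasi-periodic displacement
#' trace: an alternating opening/closing movement built cycle by cycle from
#' asymmetric half-cosine ramps, with linear per-cycle decays (sequence
#' effect), multiplicative log-normal per-cycle jitter, and additive white
#' measurement noise.
#'
#' Defaults describe a moderately impaired OFF-state hand movement: 1 unit
#' opening extent, 2 cycles/s, a mild sequence effect and per-cycle
#' variability around 5-8%, sampled at 60 Hz for 10 s (camera frame rates of
#' at least 30 Hz are assumed throughout).
#'
#' @param sampling_rate Sampling rate in Hz (>= 30).
#' @param duration Trace length in seconds; must allow at least 3 cycles at
#'   `base_frequency`.
#' @param base_amplitude Peak displacement of the first cycle (arbitrary
#'   units, > 0).
#' @param base_frequency Movement rate in cycles/second (> 0).
#' @param opening_fraction Fraction of each cycle spent opening, in (0, 1).
#' @param amplitude_decay_rate,velocity_decay_rate,frequency_decay_rate
#'   Proportional loss per cycle (>= 0) of amplitude, peak speed and
#'   movement rate respectively.  Amplitude and velocity decay shrink the
#'   within-cycle excursion; frequency decay lengthens successive cycle
#'   durations as `T_k = T0 * (1 + rate * k)`.
#' @param amplitude_jitter_cv,duration_jitter_cv Coefficient of variation of
#'   the multiplicative mean-one log-normal per-cycle jitter on amplitude and
#'   duration (>= 0).
#' @param noise_sd Standard deviation of additive white Gaussian measurement
#'   noise, displacement units (>= 0).
#' @return An object of class `signal_spec`.
#' @seealso [simulate_signal()], [condition_effect()]
#' @export
signal_spec <- function(sampling_rate = 60,
                        duration = 10,
                        base_amplitude = 1,
                        base_frequency = 2,
                        opening_fraction = 0.45,
                        amplitude_decay_rate = 0.005,
                        velocity_decay_rate = 0,
                        frequency_decay_rate = 0.005,
                        amplitude_jitter_cv = 0.08,
                        duration_jitter_cv = 0.05,
                        noise_sd = 0.01) {
  check_number(sampling_rate, "sampling_rate", lower = 30)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(base_amplitude, "base_amplitude", lower = 0, strict_lower = TRUE)
  check_number(base_frequency, "base_frequency", lower = 0, strict_lower = TRUE)
  check_number(opening_fraction, "opening_fraction",
               lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(amplitude_decay_rate, "amplitude_decay_rate", lower = 0)
  check_number(velocity_decay_rate, "velocity_decay_rate", lower = 0)
  check_number(frequency_decay_rate, "frequency_decay_rate", lower = 0)
  check_number(amplitude_jitter_cv, "amplitude_jitter_cv", lower = 0)
  check_number(duration_jitter_cv, "duration_jitter_cv", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (duration * base_frequency < 3) {
    stop_kinemed(
      "`duration` too short: fewer than 3 cycles at `base_frequency`",
      "kinemed_validation_error"
    )
  }
  structure(
    list(
      sampling_rate = sampling_rate, duration = duration,
      base_amplitude = base_amplitude, base_frequency = base_frequency,
      opening_fraction = opening_fraction,
      amplitude_decay_rate = amplitude_decay_rate,
      velocity_decay_rate = velocity_decay_rate,
      frequency_decay_rate = frequency_decay_rate,
      amplitude_jitter_cv = amplitude_jitter_cv,
      duration_jitter_cv = duration_jitter_cv,
      noise_sd = noise_sd
    ),
    class = "signal_spec"
  )
}

#' @export
print.signal_spec <- function(x, ...) {
  cat("<signal_spec>",
      sprintf("%g Hz, %g s, A0 = %g, f0 = %g cyc/s, opening %g",
              x$sampling_rate, x$duration, x$base_amplitude,
              x$base_frequency, x$opening_fraction), "\n")
  cat(sprintf("  decay/cycle: amp %g, vel %g, freq %g | jitter CV: amp %g, dur %g | noise sd %g\n",
              x$amplitude_decay_rate, x$velocity_decay_rate,
              x$frequency_decay_rate, x$amplitude_jitter_cv,
              x$duration_jitter_cv, x$noise_sd))
  invisible(x)
}

#' Multiplicative ON-state medication effect
#'
#' Factors applied to the generative parameters of a [signal_spec()] when a
#' recording is simulated in the medication ON state; the OFF state is the
#' identity (all factors 1) and is the reference level throughout the
#' package.
#'
#' `speed_factor` acts on the base movement frequency, so it raises both the
#' movement rate and (through the amplitude/duration ratio) every peak-speed
#' metric by the same factor; `amplitude_factor` scales the movement extent
#' (and thereby speeds, multiplicatively); `jitter_factor` scales both
#' per-cycle jitter CVs (values < 1 mean more consistent movements ON);
#' `decay_factor` scales all three decay rates (values < 1 mean a weaker
#' sequence effect ON).
#'
#' @param amplitude_factor,speed_factor,jitter_factor,decay_factor Positive
#'   multiplicative factors; all default to 1 (no effect).
#' @return An object of class `condition_effect`.
#' @export
#' @examples
#' condition_effect(speed_factor = 1.15)
condition_effect <- function(amplitude_factor = 1, speed_factor = 1,
                             jitter_factor = 1, decay_factor = 1) {
  for (nm in c("amplitude_factor", "speed_factor",
               "jitter_factor", "decay_factor")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  structure(
    list(amplitude_factor = amplitude_factor, speed_factor = speed_factor,
         jitter_factor = jitter_factor, decay_factor = decay_factor),
    class = "condition_effect"
  )
}

#' @export
print.condition_effect <- function(x, ...) {
  cat(sprintf(
    "<condition_effect> amplitude x%g, speed x%g, jitter x%g, decay x%g\n",
    x$amplitude_factor, x$speed_factor, x$jitter_factor, x$decay_factor))
  invisible(x)
}

# Apply an ON-state effect to a signal spec; identity for the OFF state.
apply_condition_effect <- function(spec, effect) {
  stopifnot(inherits(spec, "signal_spec"), inherits(effect, "condition_effect"))
  s <- unclass(spec)
  s$base_amplitude <- s$base_amplitude * effect$amplitude_factor
  s$base_frequency <- s$base_frequency * effect$speed_factor
  s$amplitude_jitter_cv <- s$amplitude_jitter_cv * effect$jitter_factor
  s$duration_jitter_cv <- s$duration_jitter_cv * effect$jitter_factor
  s$amplitude_decay_rate <- s$amplitude_decay_rate * effect$decay_factor
  s$velocity_decay_rate <- s$velocity_decay_rate * effect$decay_factor
  s$frequency_decay_rate <- s$frequency_decay_rate * effect$decay_factor
  class(s) <- "signal_spec"
  s
}

#' Specification of a synthetic patient cohort
#'
#' Cohort-level structure for [simulate_cohort()]: number of patients,
#' a truncated-normal number of visits per patient, the age distribution,
#' patient-level multiplicative heterogeneity (which the downstream mixed
#' model absorbs as an approximately additive random intercept), a
#' multiplicative per-year age trend on the speed parameters, and the task
#' list.  Defaults reproduce the structure of the clinical archive the
#' package emulates: 154 patients, 4.42 +/- 2.39 visits each, age 61 +/- 7.8
#' years at first visit, both tasks, one OFF and one ON recording per visit
#' and task.
#'
#' @param n_patients Number of patients (>= 1).
#' @param visits_mean,visits_sd Mean and SD of visits per patient; draws are
#'   rounded and truncated below at 1.
#' @param age_mean,age_sd Age (years) at first visit; draws are truncated to
#'   `[40, 85]`.
#' @param visit_interval_years Spacing between consecutive visits (years).
#' @param patient_intercept_sd SD (log scale) of the patient-level
#'   multiplicative intercept applied to base amplitude and frequency (>= 0).
#' @param age_slope Per-year log-linear trend on the speed parameters
#'   (negative values slow older patients).
#' @param tasks Character vector of task labels.
#' @param dropout_prob Probability that an individual ON recording is
#'   missing (models incomplete challenge sessions); 0 keeps the design
#'   fully balanced.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 154,
                        visits_mean = 4.42, visits_sd = 2.39,
                        age_mean = 61, age_sd = 7.8,
                        visit_interval_years = 0.42,
                        patient_intercept_sd = 0.12,
                        age_slope = -0.005,
                        tasks = c("finger_tapping", "hand_opening"),
                        dropout_prob = 0,
                        seed = 1L) {
  check_number(n_patients, "n_patients", lower = 1)
  check_number(visits_mean, "visits_mean", lower = 1)
  check_number(visits_sd, "visits_sd", lower = 0)
  check_number(age_mean, "age_mean", lower = 0, strict_lower = TRUE)
  check_number(age_sd, "age_sd", lower = 0)
  check_number(visit_interval_years, "visit_interval_years", lower = 0)
  check_number(patient_intercept_sd, "patient_intercept_sd", lower = 0)
  check_number(age_slope, "age_slope")
  check_number(dropout_prob, "dropout_prob", lower = 0, upper = 1)
  stopifnot(is.character(tasks), length(tasks) >= 1)
  structure(
    list(n_patients = as.integer(n_patients),
         visits_mean = visits_mean, visits_sd = visits_sd,
         age_mean = age_mean, age_sd = age_sd,
         visit_interval_years = visit_interval_years,
         patient_intercept_sd = patient_intercept_sd,
         age_slope = age_slope, tasks = tasks,
         dropout_prob = dropout_prob, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d patients, visits ~ N(%g, %g) >= 1, age ~ N(%g, %g)\n",
    x$n_patients, x$visits_mean, x$visits_sd, x$age_mean, x$age_sd))
  cat(sprintf("  intercept sd %g, age slope %g/yr, tasks: %s, dropout %g, seed %d\n",
              x$patient_intercept_sd, x$age_slope,
              paste(x$tasks, collapse = ", "), x$dropout_prob, x$seed))
  invisible(x)
}
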