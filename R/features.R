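#' The canonical kinematic feature set
#'
#' Names of the kinematic features extracted from one recording.  The default
#' canon (`"core"`) is the set of twenty features that enters the
#' statistical analyses (and over which the Bonferroni correction is taken);
#' `"full"` appends three further coefficient-of-variation metrics
#' (`cv_rms_velocity`, `cv_opening_speed`, `cv_closing_speed`) that are
#' computed by [extract_features()] but excluded from the default canon.
#'
#' The features fall into five families:
#' * **Scale/speed means**: `mean_amplitude`, `mean_speed` (per-cycle peak
#'   absolute velocity), `mean_rms_velocity`, `mean_opening_speed`,
#'   `mean_closing_speed`.
#' * **Rhythm**: `mean_cycle_duration`, `frequency` (cycles per second of
#'   spanned movement time).
#' * **Sequence effect**: `amplitude_decay`, `velocity_decay`,
#'   `frequency_decay` — proportional change per cycle (OLS slope over cycle
#'   index divided by fitted intercept) of amplitude, peak speed, and
#'   instantaneous rate 1/duration respectively; negative values indicate
#'   decrement across repetitions.
#' * **Absolute variability**: `sd_amplitude`, `sd_speed`, `sd_rms_velocity`,
#'   `sd_opening_speed`, `sd_closing_speed`, `sd_cycle_duration`,
#'   `range_cycle_duration`.
#' * **Relative variability**: `cv_amplitude`, `cv_cycle_duration`,
#'   `cv_speed` (SD divided by mean).
#'
#' @param canon `"core"` (default, 20 features) or `"full"` (23).
#' @return Character vector of feature names, in canonical order.
#' @export
#' @examples
#' kinematic_features()
kinematic_features <- function(canon = c("core", "full")) {
  canon <- match.arg(canon)
  base <- c(
    "mean_amplitude", "mean_speed", "mean_rms_velocity",
    "mean_opening_speed", "mean_closing_speed", "mean_cycle_duration",
    "frequency",
    "amplitude_decay", "velocity_decay", "frequency_decay",
    "sd_amplitude", "sd_speed", "sd_rms_velocity",
    "sd_opening_speed", "sd_closing_speed", "sd_cycle_duration",
    "range_cycle_duration",
    "cv_amplitude", "cv_cycle_duration", "cv_speed"
  )
  if (canon == "full") {
    base <- c(base, "cv_rms_velocity", "cv_opening_speed", "cv_closing_speed")
  }
  base
}
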