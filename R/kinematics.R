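#' Extraction configuration
#'
#' Tunable parameters of the feature-extraction stage.
#'
#' @param smoothing_window Width (seconds) of the zero-phase Savitzky-Golay
#'   smoother applied to the displacement before differentiation; 0 disables
#'   smoothing.
#' @param min_prominence_fraction Peaks/valleys must have topographic
#'   prominence of at least this fraction of the global displacement range.
#' @param min_cycle_duration Shortest admissible cycle, seconds.
#' @param canon Feature canon passed to [kinematic_features()].
#' @return A list of class `kin_config`.
#' @export
kin_config <- function(smoothing_window = 0.1,
                       min_prominence_fraction = 0.2,
                       min_cycle_duration = 0.1,
                       canon = "core") {
  check_number(smoothing_window, "smoothing_window", lower = 0)
  check_number(min_prominence_fraction, "min_prominence_fraction",
               lower = 0, upper = 1)
  check_number(min_cycle_duration, "min_cycle_duration", lower = 0)
  structure(list(smoothing_window = smoothing_window,
                 min_prominence_fraction = min_prominence_fraction,
                 min_cycle_duration = min_cycle_duration,
                 canon = canon),
            class = "kin_config")
}

#' Smooth a displacement trace and compute its velocity
#'
#' Applies a zero-phase low-pass moving filter (third-order Savitzky-Golay,
#' odd window of `smoothing_window` seconds) to the displacement and derives
#' the velocity by central finite differences scaled by the sampling rate
#' (one-sided differences at the ends).  Output lengths equal the input
#' length.
#'
#' @param signal A `movement_signal` (from [simulate_signal()] or
#'   [read_signal_csv()]), or a numeric vector if `sampling_rate` is given.
#' @param smoothing_window Window in seconds; windows shorter than 2 samples
#'   (but positive) trigger a warning and leave the trace unsmoothed; 0
#'   disables smoothing silently.
#' @param sampling_rate Required when `signal` is a bare numeric vector.
#' @return List with `displacement` (smoothed), `velocity` and
#'   `sampling_rate`.
#' @export
preprocess <- function(signal, smoothing_window = 0.1, sampling_rate = NULL) {
  if (inherits(signal, "movement_signal")) {
    x <- signal$displacement
    fs <- signal$sampling_rate
  } else {
    x <- as.numeric(signal)
    fs <- sampling_rate
    if (is.null(fs)) {
      stop_kinemed("`sampling_rate` required for a bare numeric trace",
                   "kinemed_validation_error")
    }
  }
  if (length(x) < fs) {
    stop_kinemed("need at least 1 s of data", "kinemed_validation_error")
  }
  if (smoothing_window > 0) {
    w <- round(smoothing_window * fs)
    if (w < 2) {
      warning("smoothing window shorter than 2 samples; trace left unsmoothed")
    } else {
      if (w %% 2 == 0) w <- w + 1
      w <- max(w, 5)  # SG order 3 needs window > order + 1
      if (w <= length(x)) {
        x <- signal::sgolayfilt(x, p = 3, n = w)
      } else {
        warning("smoothing window longer than the trace; left unsmoothed")
      }
    }
  }
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  list(displacement = x, velocity = v, sampling_rate = fs)
}

# Local maxima of `x` with topographic prominence >= min_prominence.
# From each candidate walk outwards until a strictly higher sample; that
# side's base is the minimum of the walked stretch.  A walk that reaches
# the trace boundary without meeting higher terrain imposes no base (open
# boundary), so extrema adjacent to the trace edges keep their full
# prominence; if neither side meets higher terrain the global minimum is
# the base.  prominence = height - max(available bases).  With
# include_endpoints = TRUE the first/last samples are candidate peaks
# (needed so traces that start/end at a valley contribute boundary valleys
# when called on the negated trace).
find_peaks <- function(x, min_prominence, include_endpoints = FALSE) {
  n <- length(x)
  if (n < 3) return(integer(0))
  interior <- which(diff(sign(diff(x))) < 0) + 1L
  # plateau-safe: keep samples strictly greater than the left neighbour and
  # at least as great as the right neighbour
  interior <- interior[x[interior] > x[interior - 1L] &
                         x[interior] >= x[interior + 1L]]
  cand <- interior
  if (include_endpoints) {
    if (x[1] >= x[2]) cand <- c(1L, cand)
    if (x[n] >= x[n - 1]) cand <- c(cand, n)
  }
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    h <- x[p]
    left_base <- NA_real_
    if (p > 1L) {
      j <- p - 1L
      m <- x[j]
      while (j > 1L && x[j] <= h) {
        j <- j - 1L
        if (x[j] < m) m <- x[j]
      }
      if (x[j] > h) left_base <- m  # contained on this side
    }
    right_base <- NA_real_
    if (p < n) {
      j <- p + 1L
      m <- x[j]
      while (j < n && x[j] <= h) {
        j <- j + 1L
        if (x[j] < m) m <- x[j]
      }
      if (x[j] > h) right_base <- m
    }
    base <- if (is.na(left_base) && is.na(right_base)) {
      min(x)
    } else {
      max(left_base, right_base, na.rm = TRUE)
    }
    keep[i] <- (h - base) >= min_prominence
  }
  cand[keep]
}

#' Segment a displacement trace into movement cycles
#'
#' Detects peaks with topographic prominence of at least
#' `min_prominence_fraction` times the global displacement range, valleys
#' likewise on the negated trace (trace endpoints may serve as boundary
#' valleys), and forms valley-peak-valley cycles.  A cycle's amplitude is
#' the peak displacement minus the mean of its two bounding valley
#' displacements — robust to slow baseline drift in markerless tracking.
#'
#' @param displacement Numeric trace (typically the smoothed output of
#'   [preprocess()]).
#' @param sampling_rate Hz.
#' @param min_prominence_fraction,min_cycle_duration See [kin_config()].
#' @return A data frame of class `cycle_set`: one row per cycle with
#'   `start`, `peak`, `end` (sample indices), `duration` (s) and
#'   `amplitude`; sampling rate kept as an attribute.
#' @section Errors: fewer than 3 complete cycles raise a condition of class
#'   `kinemed_insufficient_cycles`, marking the recording unusable.
#' @export
segment_cycles <- function(displacement, sampling_rate,
                           min_prominence_fraction = 0.2,
                           min_cycle_duration = 0.1) {
  x <- as.numeric(displacement)
  rng <- max(x) - min(x)
  if (!is.finite(rng) || rng <= 0) {
    stop_kinemed("insufficient cycles: trace has no oscillation",
                 "kinemed_insufficient_cycles")
  }
  prom <- min_prominence_fraction * rng
  peaks <- find_peaks(x, prom, include_endpoints = FALSE)
  valleys <- find_peaks(-x, prom, include_endpoints = TRUE)
  starts <- pks <- ends <- integer(0)
  if (length(valleys) >= 2 && length(peaks) >= 1) {
    for (i in seq_len(length(valleys) - 1L)) {
      v1 <- valleys[i]
      v2 <- valleys[i + 1L]
      inside <- peaks[peaks > v1 & peaks < v2]
      if (!length(inside)) next
      pk <- inside[which.max(x[inside])]
      if ((v2 - v1) / sampling_rate < min_cycle_duration) next
      if (x[pk] - (x[v1] + x[v2]) / 2 <= 0) next
      starts <- c(starts, v1); pks <- c(pks, pk); ends <- c(ends, v2)
    }
  }
  if (length(starts) < 3L) {
    stop_kinemed(sprintf(
      "insufficient cycles: %d complete cycles detected (need >= 3)",
      length(starts)), "kinemed_insufficient_cycles")
  }
  out <- data.frame(start = starts, peak = pks, end = ends,
                    duration = (ends - starts) / sampling_rate,
                    amplitude = x[pks] - (x[starts] + x[ends]) / 2)
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("cycle_set", "data.frame")
  out
}

# Maximum of a sampled segment with sub-sample refinement: least-squares
# parabola over up to 2*w+1 samples around the discrete maximum.  A bare
# discrete max undershoots a smooth extremum by O((f*dt)^2) at camera frame
# rates, while a 3-point interpolation inherits the full noise of the top
# sample; the windowed fit does neither.
.seg_max <- function(y, w = 3L) {
  i <- which.max(y)
  lo <- max(1L, i - w)
  hi <- min(length(y), i + w)
  if (hi - lo < 2L) return(y[i])
  k <- (lo:hi) - i
  b <- stats::lm.fit(cbind(1, k, k^2), y[lo:hi])$coefficients
  if (!is.finite(b[3]) || b[3] >= 0) return(y[i])  # not locally concave
  vertex <- -b[2] / (2 * b[3])
  if (abs(vertex) > w) return(y[i])                # fit does not bracket a peak
  unname(b[1] - b[2]^2 / (4 * b[3]))
}

#' Fill per-cycle velocity metrics
#'
#' For each segmented cycle computes the opening speed (maximum velocity
#' between start valley and peak), closing speed (maximum of the negated
#' velocity between peak and end valley), cycle speed (maximum absolute
#' velocity over the whole cycle) and RMS velocity.  Velocity extrema are
#' refined by parabolic interpolation around the discrete maximum; the RMS
#' is taken over the half-open cycle window so shared boundary valleys are
#' not double-weighted.
#'
#' @param cycles A `cycle_set` from [segment_cycles()].
#' @param velocity Velocity trace from [preprocess()] (same length as the
#'   segmented displacement).
#' @return The `cycle_set` with columns `opening_speed`, `closing_speed`,
#'   `speed`, `rms_velocity` added.
#' @export
per_cycle_metrics <- function(cycles, velocity) {
  stopifnot(inherits(cycles, "cycle_set"))
  v <- as.numeric(velocity)
  n <- nrow(cycles)
  op <- cl <- sp <- rms <- numeric(n)
  for (i in seq_len(n)) {
    a <- cycles$start[i]; p <- cycles$peak[i]; b <- cycles$end[i]
    op[i] <- .seg_max(v[a:p])
    cl[i] <- .seg_max(-v[p:b])
    sp[i] <- max(op[i], cl[i], abs(v[a:b]))
    rms[i] <- sqrt(mean(v[a:(b - 1L)]^2))
  }
  cycles$opening_speed <- op
  cycles$closing_speed <- cl
  cycles$speed <- sp
  cycles$rms_velocity <- rms
  cycles
}

# OLS slope / fitted intercept of y against 0-based cycle index:
# proportional change per cycle, scale-free.
.decay_slope <- function(y) {
  k <- seq_along(y) - 1
  fit <- stats::lm.fit(cbind(1, k), y)
  b0 <- fit$coefficients[1]
  if (!is.finite(b0) || abs(b0) < .Machine$double.eps^0.5) {
    warning("decay intercept is ~0; decay reported as NA")
    return(NA_real_)
  }
  unname(fit$coefficients[2] / b0)
}

.cv <- function(s, m, what) {
  if (!is.finite(m) || m == 0) {
    warning(sprintf("mean %s is 0; CV reported as NA", what))
    return(NA_real_)
  }
  s / m
}

#' Aggregate per-cycle metrics into the kinematic feature vector
#'
#' Means and standard deviations over cycles for amplitude, speed, RMS
#' velocity, opening/closing speed and cycle duration; `frequency` as the
#' number of cycles divided by the time spanned from the first start valley
#' to the last end valley (less biased under jitter than 1/mean duration);
#' `range_cycle_duration` as max minus min duration; CVs as SD/mean; decays
#' as the OLS slope of the per-cycle metric (amplitude, cycle speed, and
#' instantaneous rate 1/duration) against cycle index divided by the fitted
#' intercept, i.e. the proportional change per cycle.
#'
#' @param cycles A `cycle_set` with metrics filled by [per_cycle_metrics()];
#'   at least 3 cycles.
#' @return Named numeric vector with the 23 features of
#'   `kinematic_features("full")`.
#' @export
aggregate_features <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"),
            !is.null(cycles$speed), nrow(cycles) >= 3)
  fs <- attr(cycles, "sampling_rate")
  span <- (cycles$end[nrow(cycles)] - cycles$start[1]) / fs
  m_amp <- mean(cycles$amplitude); s_amp <- sd(cycles$amplitude)
  m_sp <- mean(cycles$speed);      s_sp <- sd(cycles$speed)
  m_rms <- mean(cycles$rms_velocity); s_rms <- sd(cycles$rms_velocity)
  m_op <- mean(cycles$opening_speed); s_op <- sd(cycles$opening_speed)
  m_cl <- mean(cycles$closing_speed); s_cl <- sd(cycles$closing_speed)
  m_dur <- mean(cycles$duration);  s_dur <- sd(cycles$duration)
  out <- c(
    mean_amplitude = m_amp,
    mean_speed = m_sp,
    mean_rms_velocity = m_rms,
    mean_opening_speed = m_op,
    mean_closing_speed = m_cl,
    mean_cycle_duration = m_dur,
    frequency = nrow(cycles) / span,
    amplitude_decay = .decay_slope(cycles$amplitude),
    velocity_decay = .decay_slope(cycles$speed),
    frequency_decay = .decay_slope(1 / cycles$duration),
    sd_amplitude = s_amp,
    sd_speed = s_sp,
    sd_rms_velocity = s_rms,
    sd_opening_speed = s_op,
    sd_closing_speed = s_cl,
    sd_cycle_duration = s_dur,
    range_cycle_duration = max(cycles$duration) - min(cycles$duration),
    cv_amplitude = .cv(s_amp, m_amp, "amplitude"),
    cv_cycle_duration = .cv(s_dur, m_dur, "cycle duration"),
    cv_speed = .cv(s_sp, m_sp, "speed"),
    cv_rms_velocity = .cv(s_rms, m_rms, "RMS velocity"),
    cv_opening_speed = .cv(s_op, m_op, "opening speed"),
    cv_closing_speed = .cv(s_cl, m_cl, "closing speed")
  )
  out
}

#' Extract the kinematic feature vector from one recording
#'
#' Composition of [preprocess()], [segment_cycles()], [per_cycle_metrics()]
#' and [aggregate_features()]; deterministic.
#'
#' @param signal A `movement_signal`.
#' @param config A [kin_config()].
#' @return Named numeric vector of features (23; subset with
#'   [kinematic_features()] for the statistical canon).
#' @export
#' @examples
#' sig <- simulate_signal(signal_spec(duration = 5, noise_sd = 0,
#'                                    amplitude_jitter_cv = 0,
#'                                    duration_jitter_cv = 0,
#'                                    amplitude_decay_rate = 0,
#'                                    frequency_decay_rate = 0), seed = 1)
#' round(extract_features(sig)[c("mean_amplitude", "frequency")], 3)
extract_features <- function(signal, config = kin_config()) {
  stopifnot(inherits(signal, "movement_signal"))
  if (!length(signal$displacement)) {
    stop_kinemed("empty signal", "kinemed_validation_error")
  }
  prep <- preprocess(signal, smoothing_window = config$smoothing_window)
  cyc <- segment_cycles(prep$displacement, prep$sampling_rate,
                        min_prominence_fraction = config$min_prominence_fraction,
                        min_cycle_duration = config$min_cycle_duration)
  cyc <- per_cycle_metrics(cyc, prep$velocity)
  aggregate_features(cyc)
}
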