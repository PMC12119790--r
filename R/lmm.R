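#' Mask upper-tail outliers in a feature table
#'
#' Per task and per feature, values strictly greater than that feature's
#' given percentile (computed over all rows of the task) are set to missing.
#' Other features of the same row are untouched and rows are never deleted
#' wholesale.  The rule is one-sided (upper tail), matching an exclusion of
#' data points *exceeding* the percentile.
#'
#' @param table A feature table data frame (long format: `patient_id`,
#'   `visit_id`, `task`, `condition`, `age_at_visit`, one column per
#'   feature).
#' @param percentile Percentile in (0, 100]; default 99.
#' @param features Feature columns to screen; defaults to the canonical
#'   names present in `table`.
#' @return The table with outliers set to `NA`; the number of masked values
#'   per feature is attached as attribute `"n_masked"`.
#' @export
exclude_outliers <- function(table, percentile = 99, features = NULL) {
  check_number(percentile, "percentile", lower = 0, upper = 100,
               strict_lower = TRUE)
  if (is.null(features)) {
    features <- intersect(kinematic_features("full"), names(table))
  }
  for (f in features) {
    if (!is.numeric(table[[f]])) {
      stop_kinemed(sprintf("feature column `%s` is not numeric", f),
                   "kinemed_validation_error")
    }
  }
  masked <- setNames(integer(length(features)), features)
  for (task in unique(table$task)) {
    sel <- table$task == task
    for (f in features) {
      x <- table[[f]][sel]
      thr <- quantile(x, percentile / 100, na.rm = TRUE, names = FALSE)
      bad <- sel & !is.na(table[[f]]) & table[[f]] > thr
      masked[f] <- masked[f] + sum(bad)
      table[[f]][bad] <- NA
    }
  }
  attr(table, "n_masked") <- masked
  table
}

#' Bonferroni threshold and flags
#'
#' @param p_values Numeric vector of per-feature p-values.
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of comparisons (default 20, the size of the feature
#'   canon).
#' @return List with `threshold = alpha / m` and logical `significant`
#'   (strict `p < threshold`).
#' @export
#' @examples
#' bonferroni(c(0.001, 0.0025, 0.04))$threshold   # 0.0025
bonferroni <- function(p_values, alpha = 0.05, m = 20) {
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_number(m, "m", lower = 1)
  thr <- alpha / m
  list(threshold = thr, significant = !is.na(p_values) & p_values < thr)
}

#' Medication effect on one feature via a linear mixed-effects model
#'
#' Fits `feature ~ condition + age_at_visit + (1 | patient_id)` by REML
#' (OFF is the reference level) and summarises the ON-vs-OFF fixed effect
#' as a Wald z coefficient with 95% CI and p-value, plus its percentage
#' change of the OFF-state baseline:
#' `percentage change = 100 * coefficient / baseline mean`, where the
#' baseline mean is the OFF-state mean of the feature after outlier
#' exclusion.  Missing feature values are dropped listwise.
#'
#' @param table Feature table (ideally after [exclude_outliers()]).
#' @param feature Feature column name.
#' @param task Optional task label to subset first.
#' @param conf_level Confidence level for the Wald interval.
#' @return Object of class `lmm_effect`: list with `feature`, `task`,
#'   `coefficient`, `se`, `ci` (length 2), `p_value`, `baseline_mean`,
#'   `pct_change`, `pct_ci`, `n_obs`, `n_patients`, `singular`,
#'   `converged`, and the fitted `model`.  Singular or non-convergent fits
#'   are returned flagged, never silently dropped.
#' @export
fit_condition_lmm <- function(table, feature, task = NULL,
                              conf_level = 0.95) {
  if (!feature %in% names(table)) {
    stop_kinemed(sprintf("unknown feature `%s`", feature),
                 "kinemed_validation_error")
  }
  if (!is.null(task)) table <- table[table$task == task, , drop = FALSE]
  d <- data.frame(
    y = table[[feature]],
    condition = factor(table$condition, levels = c("OFF", "ON")),
    age_at_visit = table$age_at_visit,
    patient_id = factor(table$patient_id)
  )
  d <- d[complete.cases(d), , drop = FALSE]
  both <- tapply(d$condition, d$patient_id,
                 function(z) length(unique(z)) == 2L)
  if (sum(both, na.rm = TRUE) < 2L) {
    stop_kinemed(
      "need >= 2 patients observed in both conditions",
      "kinemed_validation_error")
  }
  conv_msgs <- character(0)
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(
      y ~ condition + age_at_visit + (1 | patient_id),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))),
    warning = function(w) {
      conv_msgs <<- c(conv_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)$coefficients
  est <- co["conditionON", "Estimate"]
  se <- co["conditionON", "Std. Error"]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- est + c(-1, 1) * zq * se
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  baseline <- mean(d$y[d$condition == "OFF"])
  structure(
    list(feature = feature, task = task,
         coefficient = est, se = se, ci = ci, p_value = p,
         baseline_mean = baseline,
         pct_change = 100 * est / baseline,
         pct_ci = 100 * ci / baseline,
         n_obs = nrow(d), n_patients = nlevels(droplevels(d$patient_id)),
         singular = lme4::isSingular(fit),
         converged = length(conv_msgs) == 0L,
         convergence_messages = conv_msgs,
         model = fit),
    class = "lmm_effect"
  )
}

#' @export
print.lmm_effect <- function(x, digits = 3, ...) {
  cat(sprintf("<lmm_effect> %s%s\n", x$feature,
              if (!is.null(x$task)) paste0(" [", x$task, "]") else ""))
  cat(sprintf("  ON - OFF: %.4g [%.4g, %.4g], p = %.3g\n",
              x$coefficient, x$ci[1], x$ci[2], x$p_value))
  cat(sprintf("  baseline (OFF) mean %.4g -> %.2f%% change [%.2f%%, %.2f%%]\n",
              x$baseline_mean, x$pct_change, x$pct_ci[1], x$pct_ci[2]))
  if (x$singular) cat("  note: singular random-effect fit\n")
  if (!x$converged) cat("  note:", x$convergence_messages, "\n")
  invisible(x)
}

#' Medication effects for a whole feature canon
#'
#' Runs [fit_condition_lmm()] for every feature and assembles the per-task
#' results table (one row per feature: coefficient, CI, p, OFF baseline,
#' percentage change with CI, Bonferroni flag).
#'
#' @param table Feature table after outlier exclusion.
#' @param task Task label to analyse.
#' @param features Feature canon (default the 20-feature canon present in
#'   the table).
#' @param alpha,m Bonferroni family-wise level and comparison count;
#'   `m` defaults to the number of features analysed.
#' @return Data frame of class `med_effect_table`.
#' @export
medication_effects <- function(table, task,
                               features = NULL,
                               alpha = 0.05, m = NULL) {
  if (is.null(features)) {
    features <- intersect(kinematic_features("core"), names(table))
  }
  if (is.null(m)) m <- length(features)
  rows <- lapply(features, function(f) {
    r <- fit_condition_lmm(table, f, task = task)
    data.frame(feature = f,
               coefficient = r$coefficient, se = r$se,
               ci_lower = r$ci[1], ci_upper = r$ci[2],
               p_value = r$p_value,
               baseline_mean = r$baseline_mean,
               pct_change = r$pct_change,
               pct_ci_lower = r$pct_ci[1], pct_ci_upper = r$pct_ci[2],
               n_obs = r$n_obs, n_patients = r$n_patients,
               singular = r$singular, converged = r$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bf <- bonferroni(out$p_value, alpha = alpha, m = m)
  out$bonferroni_significant <- bf$significant
  attr(out, "task") <- task
  attr(out, "bonferroni_threshold") <- bf$threshold
  class(out) <- c("med_effect_table", "data.frame")
  out
}

#' @export
print.med_effect_table <- function(x, digits = 3, ...) {
  needed <- c("feature", "pct_change", "pct_ci_lower", "pct_ci_upper",
              "p_value", "bonferroni_significant")
  if (!all(needed %in% names(x))) {      # subset of columns: plain printing
    return(print.data.frame(x, digits = digits, ...))
  }
  cat(sprintf("Medication effects (ON vs OFF), task: %s\n", attr(x, "task")))
  cat(sprintf("Bonferroni threshold p < %g\n\n",
              attr(x, "bonferroni_threshold")))
  d <- data.frame(
    feature = x$feature,
    `pct change` = sprintf("%.2f%% [%.2f%%, %.2f%%]", x$pct_change,
                           x$pct_ci_lower, x$pct_ci_upper),
    p = signif(x$p_value, 3),
    sig = ifelse(x$bonferroni_significant, "yes", ""),
    check.names = FALSE
  )
  print(d, row.names = FALSE)
  invisible(x)
}

.p_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Cross-task effect report
#'
#' Combines per-task medication-effect tables into (i) a Table-style long
#' report, (ii) the subset of features whose absolute percentage change
#' exceeds `threshold_pct` in *every* task, and (iii) signed bar-chart data
#' with significance annotation.  Features missing from any task are
#' excluded with a warning.
#'
#' @param results Named list (task -> `med_effect_table` or data frame with
#'   at least `feature`, `pct_change`, `p_value`).
#' @param threshold_pct Threshold on |percentage change| (default 10).
#' @return Object of class `effect_report`: list with `table`,
#'   `strong_features`, `bar_data`, `threshold_pct`.
#' @export
report_effects <- function(results, threshold_pct = 10) {
  stopifnot(is.list(results), length(results) >= 1, !is.null(names(results)))
  feats <- lapply(results, function(r) r$feature)
  common <- Reduce(intersect, feats)
  missing <- setdiff(unique(unlist(feats)), common)
  if (length(missing)) {
    warning("features not present in every task excluded from the report: ",
            paste(missing, collapse = ", "))
  }
  long <- do.call(rbind, lapply(names(results), function(task) {
    r <- results[[task]]
    r <- r[r$feature %in% common, , drop = FALSE]
    data.frame(task = task, feature = r$feature,
               pct_change = r$pct_change,
               p_value = r$p_value,
               bonferroni_significant =
                 if (!is.null(r$bonferroni_significant))
                   r$bonferroni_significant else NA,
               stars = .p_stars(r$p_value),
               stringsAsFactors = FALSE)
  }))
  strong <- common[vapply(common, function(f) {
    all(vapply(results, function(r) {
      abs(r$pct_change[r$feature == f]) > threshold_pct
    }, logical(1)))
  }, logical(1))]
  structure(list(table = long, strong_features = strong,
                 bar_data = long, threshold_pct = threshold_pct),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat(sprintf("<effect_report> %d features x %d tasks\n",
              length(unique(x$table$feature)),
              length(unique(x$table$task))))
  cat(sprintf("Features with |pct change| > %g%% in all tasks:\n",
              x$threshold_pct))
  if (length(x$strong_features)) {
    cat(paste0("  ", x$strong_features, collapse = "\n"), "\n")
  } else {
    cat("  (none)\n")
  }
  invisible(x)
}
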