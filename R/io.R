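# File formats: per-recording displacement CSV (time_s, displacement) with a
# JSON metadata sidecar, and the long-format feature table CSV.

#' Write / read a displacement trace as CSV
#'
#' The CSV has columns `time_s` and `displacement`; task, sampling rate and
#' recording metadata go to a JSON sidecar `<path>.json`.
#'
#' @param signal A `movement_signal`.
#' @param path CSV path.
#' @return `write_signal_csv()` the path, invisibly; `read_signal_csv()` a
#'   `movement_signal`.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "movement_signal"))
  n <- length(signal$displacement)
  d <- data.frame(time_s = (seq_len(n) - 1) / signal$sampling_rate,
                  displacement = signal$displacement)
  write.csv(d, path, row.names = FALSE)
  side <- list(sampling_rate = signal$sampling_rate, task = signal$task,
               meta = signal$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_s", "displacement") %in% names(d))) {
    stop_kinemed("signal CSV must have columns time_s, displacement",
                 "kinemed_validation_error")
  }
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    fs <- side$sampling_rate
    task <- side$task
    meta <- as.list(side$meta)
  } else {
    dt <- diff(d$time_s)
    fs <- 1 / stats::median(dt)
    task <- "unknown"
    meta <- list()
  }
  structure(list(displacement = d$displacement, sampling_rate = fs,
                 task = task, meta = meta,
                 cycles = NULL),
            class = "movement_signal")
}

#' Extract a feature table from a collection of recordings
#'
#' Runs [extract_features()] on every signal and assembles the long-format
#' cohort table (one row per recording).  Recordings that fail cycle
#' segmentation are dropped with a message, never silently.
#'
#' @param signals A `synthetic_cohort` or a list of `movement_signal`
#'   objects whose `meta` carries `patient_id`, `visit_id`, `condition` and
#'   `age_at_visit`.
#' @param config A [kin_config()].
#' @return Data frame: `recording_id`, `patient_id`, `visit_id`, `task`,
#'   `condition`, `age_at_visit`, plus one column per extracted feature.
#' @export
extract_feature_table <- function(signals, config = kin_config()) {
  if (inherits(signals, "synthetic_cohort")) signals <- signals$signals
  stopifnot(is.list(signals), length(signals) >= 1)
  feat_names <- kinematic_features("full")
  fmat <- matrix(NA_real_, length(signals), length(feat_names),
                 dimnames = list(NULL, feat_names))
  rid <- pid <- task <- cond <- character(length(signals))
  vid <- integer(length(signals))
  age <- numeric(length(signals))
  ok <- logical(length(signals))
  for (i in seq_along(signals)) {
    sig <- signals[[i]]
    fv <- tryCatch(extract_features(sig, config),
                   kinemed_insufficient_cycles = function(e) NULL)
    if (is.null(fv)) next
    ok[i] <- TRUE
    fmat[i, names(fv)] <- fv
    meta <- sig$meta
    rid[i] <- meta$recording_id %||% names(signals)[i] %||% sprintf("R%05d", i)
    pid[i] <- meta$patient_id %||% NA_character_
    vid[i] <- meta$visit_id %||% NA_integer_
    task[i] <- sig$task
    cond[i] <- meta$condition %||% NA_character_
    age[i] <- meta$age_at_visit %||% NA_real_
  }
  if (any(!ok)) {
    message(sprintf(
      "extract_feature_table: %d recording(s) unusable (insufficient cycles)",
      sum(!ok)))
  }
  out <- data.frame(recording_id = rid[ok], patient_id = pid[ok],
                    visit_id = vid[ok], task = task[ok],
                    condition = cond[ok], age_at_visit = age[ok],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(fmat[ok, , drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a long-format feature table from delimited text
#'
#' Maps external column names onto the canonical schema via a user-supplied
#' mapping, normalises condition labels to `OFF`/`ON`, validates mandatory
#' columns and reports what was dropped or ignored.
#'
#' @param path Delimited text file with a header.
#' @param column_map Optional named character vector
#'   `c(canonical = "external", ...)` renaming external columns.
#' @param condition_map Optional named character vector mapping external
#'   condition labels to `"OFF"`/`"ON"` (e.g.
#'   `c("Med OFF" = "OFF", "Med ON" = "ON")`).
#' @param sep Field separator (default `,`).
#' @return Feature table data frame.
#' @export
read_feature_table <- function(path, column_map = NULL,
                               condition_map = NULL, sep = ",") {
  d <- read.csv(path, sep = sep, check.names = FALSE,
                stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      ext <- column_map[[canonical]]
      if (!ext %in% names(d)) {
        stop_kinemed(sprintf("mapped column `%s` not found in file", ext),
                     "kinemed_validation_error")
      }
      names(d)[names(d) == ext] <- canonical
    }
  }
  mandatory <- c("patient_id", "condition", "task")
  miss <- setdiff(mandatory, names(d))
  if (length(miss)) {
    stop_kinemed(sprintf(
      "mandatory column(s) missing: %s; available columns: %s",
      paste(miss, collapse = ", "), paste(names(d), collapse = ", ")),
      "kinemed_validation_error")
  }
  if (!is.null(condition_map)) {
    mapped <- unname(condition_map[as.character(d$condition)])
    d$condition[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  bad <- !d$condition %in% c("OFF", "ON")
  if (any(bad)) {
    message(sprintf("read_feature_table: %d row(s) with unrecognised condition dropped",
                    sum(bad)))
    d <- d[!bad, , drop = FALSE]
  }
  known <- c("recording_id", "patient_id", "visit_id", "task", "condition",
             "age_at_visit", kinematic_features("full"))
  extra <- setdiff(names(d), known)
  if (length(extra)) {
    message("read_feature_table: ignoring extra column(s): ",
            paste(extra, collapse = ", "))
  }
  d
}

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline; round-trips losslessly
#' through JSON via [write_run_config()] / [read_run_config()].
#'
#' @param seed Master seed for the run.
#' @param tasks Task labels to analyse.
#' @param canon `"core"` or `"full"` feature canon.
#' @param cohort,off_spec,on_effect Simulation inputs (ignored when
#'   `input_feature_table` is given).
#' @param input_feature_table Optional path to an existing feature-table
#'   CSV; when set, simulation and extraction are skipped.
#' @param extraction A [kin_config()].
#' @param outlier_percentile Upper-tail exclusion percentile.
#' @param alpha,m_comparisons Bonferroni settings (`m_comparisons = NULL`
#'   uses the canon size).
#' @param spca_penalty L1 penalty for [fit_sparse_pca()].
#' @param spca_components Explicit component count, or `NULL` for the elbow
#'   rule.
#' @param spca_max_components Components fitted before the elbow is
#'   assessed.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       tasks = c("finger_tapping", "hand_opening"),
                       canon = "core",
                       cohort = cohort_spec(seed = seed),
                       off_spec = signal_spec(),
                       on_effect = condition_effect(amplitude_factor = 1.05,
                                                    speed_factor = 1.11,
                                                    jitter_factor = 0.85,
                                                    decay_factor = 0.95),
                       input_feature_table = NULL,
                       extraction = kin_config(),
                       outlier_percentile = 99,
                       alpha = 0.05, m_comparisons = NULL,
                       spca_penalty = 1,
                       spca_components = NULL,
                       spca_max_components = 8L) {
  features <- kinematic_features(canon)
  structure(
    list(seed = as.integer(seed), tasks = tasks, canon = canon,
         features = features,
         cohort = cohort, off_spec = off_spec, on_effect = on_effect,
         input_feature_table = input_feature_table,
         extraction = extraction,
         outlier_percentile = outlier_percentile,
         alpha = alpha, m_comparisons = m_comparisons,
         spca_penalty = spca_penalty,
         spca_components = spca_components,
         spca_max_components = as.integer(spca_max_components)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  plain <- strip(config)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(
    seed = raw$seed, tasks = raw$tasks, canon = raw$canon,
    cohort = do.call(cohort_spec, as.list(raw$cohort)),
    off_spec = do.call(signal_spec, as.list(raw$off_spec)),
    on_effect = do.call(condition_effect, as.list(raw$on_effect)),
    input_feature_table = raw$input_feature_table,
    extraction = do.call(kin_config, as.list(raw$extraction)),
    outlier_percentile = raw$outlier_percentile,
    alpha = raw$alpha, m_comparisons = raw$m_comparisons,
    spca_penalty = raw$spca_penalty,
    spca_components = raw$spca_components,
    spca_max_components = raw$spca_max_components
  )
  cfg
}
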