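#' Run the end-to-end medication-response pipeline
#'
#' Executes the full analysis on either a simulated cohort or an ingested
#' feature table: simulate (or read) -> extract features -> upper-tail
#' outlier exclusion -> per-feature mixed-effects medication effects per
#' task -> ON-OFF differences -> standardization -> sparse PCA -> cross-task
#' loading stability.  Every artifact is written under `out_dir` together
#' with a manifest (resolved configuration, seed, config hash, row counts),
#' and identical configuration + seed reproduce identical outputs.
#'
#' Artifacts written: `features.csv`, `effects_<task>.csv`,
#' `strong_features.json`, `loadings_<task>.csv`, `cumvar_<task>.csv`,
#' `stability.csv`, `manifest.json`, `run_config.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return Object of class `kinemed_run`: list with `feature_table`,
#'   `effects` (per task), `report`, `spca` (per task), `n_components`,
#'   `stability` (data frame), `config`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  unknown <- setdiff(config$features, kinematic_features("full"))
  if (length(unknown)) {
    stop_kinemed(paste("unknown feature name(s) in config:",
                       paste(unknown, collapse = ", ")),
                 "kinemed_validation_error")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  # --- input: simulate or ingest -------------------------------------------
  if (is.null(config$input_feature_table)) {
    cohort <- config$cohort
    cohort$seed <- config$seed
    sim <- simulate_cohort(cohort, config$off_spec, config$on_effect)
    tab <- extract_feature_table(sim, config$extraction)
  } else {
    tab <- read_feature_table(config$input_feature_table)
  }
  tasks <- intersect(config$tasks, unique(tab$task))
  if (!length(tasks)) {
    stop_kinemed("no configured task present in the feature table",
                 "kinemed_validation_error")
  }
  features <- intersect(config$features, names(tab))

  # --- outlier exclusion + per-task LMMs -----------------------------------
  tab_x <- exclude_outliers(tab, percentile = config$outlier_percentile,
                            features = features)
  m <- config$m_comparisons %||% length(features)
  effects <- lapply(tasks, function(task) {
    medication_effects(tab_x, task = task, features = features,
                       alpha = config$alpha, m = m)
  })
  names(effects) <- tasks
  report <- report_effects(effects)

  # --- differences + sparse PCA per task -----------------------------------
  spca_fits <- list()
  for (task in tasks) {
    dm <- compute_differences(tab_x, task, features = features)
    z <- standardize(dm)
    kmax <- min(config$spca_max_components, ncol(z), nrow(z) - 1L)
    spca_fits[[task]] <- fit_sparse_pca(z, n_components = kmax,
                                        l1_penalty = config$spca_penalty)
  }
  n_comp <- select_n_components(spca_fits[[1]]$cum_var,
                                override = config$spca_components)
  n_comp <- min(n_comp, min(vapply(spca_fits,
                                   function(f) ncol(f$loadings), 1L)))

  stability <- NULL
  if (length(tasks) >= 2) {
    pairs <- utils::combn(tasks, 2, simplify = FALSE)
    rows <- list()
    for (pr in pairs) {
      for (j in seq_len(n_comp)) {
        st <- loading_stability(spca_fits[[pr[1]]], spca_fits[[pr[2]]], j)
        rows[[length(rows) + 1L]] <- data.frame(
          task_a = pr[1], task_b = pr[2], component = j,
          r = st$r, p_value = st$p_value, n_features = st$n_features,
          stringsAsFactors = FALSE)
      }
    }
    stability <- do.call(rbind, rows)
  }

  # --- artifacts -----------------------------------------------------------
  if (!is.null(out_dir)) {
    write.csv(tab, file.path(out_dir, "features.csv"), row.names = FALSE)
    for (task in tasks) {
      write.csv(effects[[task]],
                file.path(out_dir, paste0("effects_", task, ".csv")),
                row.names = FALSE)
      ld <- data.frame(feature = rownames(spca_fits[[task]]$loadings),
                       spca_fits[[task]]$loadings, check.names = FALSE)
      write.csv(ld, file.path(out_dir, paste0("loadings_", task, ".csv")),
                row.names = FALSE)
      write.csv(data.frame(component = seq_along(spca_fits[[task]]$cum_var),
                           ev_fraction = spca_fits[[task]]$ev_fraction,
                           cumulative = spca_fits[[task]]$cum_var),
                file.path(out_dir, paste0("cumvar_", task, ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(
      list(threshold_pct = report$threshold_pct,
           strong_features = report$strong_features),
      file.path(out_dir, "strong_features.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(stability)) {
      write.csv(stability, file.path(out_dir, "stability.csv"),
                row.names = FALSE)
    }
    cfg_path <- file.path(out_dir, "run_config.json")
    write_run_config(config, cfg_path)
    manifest <- list(
      seed = config$seed,
      config_file = "run_config.json",
      config_md5 = unname(tools::md5sum(cfg_path)),
      tasks = tasks,
      n_recordings = nrow(tab),
      n_patients = length(unique(tab$patient_id)),
      n_components = n_comp,
      outlier_percentile = config$outlier_percentile,
      artifacts = list.files(out_dir)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(feature_table = tab, feature_table_excluded = tab_x,
         effects = effects, report = report,
         spca = spca_fits, n_components = n_comp,
         stability = stability, config = config, out_dir = out_dir),
    class = "kinemed_run"
  )
}

#' @export
print.kinemed_run <- function(x, ...) {
  cat(sprintf("<kinemed_run> %d recordings, tasks: %s, %d components retained\n",
              nrow(x$feature_table),
              paste(names(x$effects), collapse = ", "), x$n_components))
  print(x$report)
  if (!is.null(x$stability)) {
    cat("Cross-task loading stability:\n")
    print(x$stability, row.names = FALSE)
  }
  invisible(x)
}
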