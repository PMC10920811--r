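#' Configuration of an end-to-end experiment run
#'
#' Bundles the cohort definition, pipeline/fold/statistics settings and a
#' master seed from which all stage seeds are derived deterministically
#' (stage-name hashing), so a single integer reproduces the entire run.
#'
#' @param cohort A `cohort_config`.
#' @param pipelines Pipelines to evaluate.
#' @param tasks Tasks to classify separately (default: the cohort's tasks).
#' @param n_folds Folds per task (default 10).
#' @param J_candidates Component counts tuned per fold.
#' @param shrinkage Covariance shrinkage.
#' @param C_grid,gbm_grid Classifier grids.
#' @param t_threshold,n_perm Cluster-test settings.
#' @param top_k Features reported from the attribution ranking.
#' @param seed Master seed.
#' @param out_dir Output directory for the report and intermediates.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       pipelines = c("supervised", "riemannian", "handcrafted"),
                       tasks = NULL,
                       n_folds = 10,
                       J_candidates = c(2, 4, 6),
                       shrinkage = 0.05,
                       C_grid = default_C_grid(),
                       gbm_grid = gbm_default_grid(),
                       t_threshold = 6,
                       n_perm = 1024,
                       top_k = 10,
                       seed = 1L,
                       out_dir = tempfile("bandcov_run_")) {
  stopifnot(inherits(cohort, "cohort_config"))
  pipelines <- match.arg(pipelines, several.ok = TRUE)
  structure(list(cohort = cohort, pipelines = pipelines,
                 tasks = tasks %||% cohort$tasks,
                 n_folds = n_folds, J_candidates = J_candidates,
                 shrinkage = shrinkage, C_grid = C_grid, gbm_grid = gbm_grid,
                 t_threshold = t_threshold, n_perm = n_perm, top_k = top_k,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# Deterministic stage seed below 2^31 from the master seed and a stage name.
stage_seed <- function(master, stage) {
  h <- as.numeric(master) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# FNV-1a hash of a string, reported as hex; used to fingerprint configs.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = 12)
  h <- 2166136261
  for (ch in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Chance-level decoding estimate over independent null cohorts
#'
#' Generates `n_cohorts` null cohorts (all planted ratios forced to 1) from a
#' template config and returns the mean test balanced accuracy of the
#' requested pipeline(s). A single finite null cohort can be genuinely
#' decodable - with few subjects per group, the random per-subject power
#' jitter realizes a nonzero group difference - so the chance level is a
#' property of the cohort *distribution* and is estimated by averaging over
#' independent cohorts.
#'
#' @param config Template `cohort_config` (effects are ignored).
#' @param pipelines Pipelines to average over.
#' @param n_cohorts Number of independent null cohorts (default 3).
#' @param n_folds Folds per cohort (default 5).
#' @param seed Base seed; cohort c uses `seed + c`.
#' @param ... Passed to [evaluate_pipeline()].
#' @return Mean held-out balanced accuracy across cohorts and pipelines,
#'   with the per-cohort, per-pipeline values in `attr(, "per_run")`.
#' @export
null_decoding_level <- function(config,
                                pipelines = c("supervised", "riemannian",
                                              "handcrafted"),
                                n_cohorts = 3, n_folds = 5, seed = 1L, ...) {
  per <- matrix(NA_real_, n_cohorts, length(pipelines),
                dimnames = list(NULL, pipelines))
  for (cc in seq_len(n_cohorts)) {
    cfg <- config
    cfg$seed <- as.integer(seed + cc)
    es <- null_cohort(cfg)
    us <- unique(es$subject)
    gg <- es$group[match(us, es$subject)]
    plan <- make_folds(us, gg, n_folds = n_folds, seed = as.integer(seed + cc))
    for (p in pipelines)
      per[cc, p] <- evaluate_pipeline(es, p, plan,
                                      seed = as.integer(seed + cc), ...)$mean_ba
  }
  out <- mean(per)
  attr(out, "per_run") <- per
  out
}

#' Run the full analysis: simulate, featurize, classify, explain, test
#'
#' Executes all stages in order on a synthetic cohort: cohort generation,
#' per-task per-pipeline subject-independent classification, pairwise model
#' comparison (Wilcoxon signed-rank on fold BA), cluster-based permutation
#' statistics on subject-level band power, activation patterns for the
#' supervised pipeline and Shapley-based top features for the handcrafted
#' pipeline. Intermediates and the consolidated report are written under
#' `config$out_dir`; a re-run with the same config reuses the cached cohort.
#'
#' @param config A `run_config`.
#' @return An object of class `run_report` (also written as
#'   `report.json` in `out_dir`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  logf("run start: config %s, master seed %d", hash, config$seed)

  # stage 1: cohort (cached on config hash)
  cache <- file.path(config$out_dir, paste0("cohort_", hash, ".rds"))
  if (file.exists(cache)) {
    cohort <- readRDS(cache)
    logf("simulate: reused cached cohort %s", cache)
  } else {
    cohort <- generate_cohort(config$cohort)
    saveRDS(cohort, cache)
    logf("simulate: generated %d epochs", n_epochs(cohort$epochs))
  }
  es <- cohort$epochs

  # stage 2: cluster statistics on subject-level band power (all tasks)
  psd <- multitaper_band_power(es, config$cohort$bands)
  sb <- summarize_psd_by_subject(psd)
  adj <- channel_adjacency(cohort$montage)
  cl <- cluster_permutation_test(sb$power, sb$groups, adj,
                                 t_threshold = config$t_threshold,
                                 n_perm = config$n_perm,
                                 seed = stage_seed(config$seed, "cluster"))
  logf("stats: %d clusters at |T| > %g", nrow(cl$clusters), config$t_threshold)

  # stage 3: classification per task x pipeline
  us <- unique(es$subject)
  ug <- es$group[match(us, es$subject)]
  results <- list()
  comparisons <- list()
  models_kept <- list()
  for (task in config$tasks) {
    plan <- make_folds(us, ug, n_folds = config$n_folds,
                       seed = stage_seed(config$seed, paste0("folds_", task)))
    per_pipe <- list()
    for (pipe in config$pipelines) {
      res <- evaluate_pipeline(es, pipe, plan, task = task,
                               bands = config$cohort$bands,
                               J_candidates = config$J_candidates,
                               shrinkage = config$shrinkage,
                               C_grid = config$C_grid,
                               gbm_grid = config$gbm_grid,
                               seed = stage_seed(config$seed,
                                                 paste0(pipe, "_", task)),
                               keep_models = pipe %in% c("supervised",
                                                         "handcrafted"))
      logf("classify: %s / %s BA %.3f +/- %.3f", task, pipe,
           res$mean_ba, res$sd_ba)
      models_kept[[paste(task, pipe, sep = "_")]] <- res$models
      res$models <- NULL
      per_pipe[[pipe]] <- res
      utils::write.csv(res$folds,
                       file.path(config$out_dir,
                                 sprintf("folds_%s_%s.csv", task, pipe)),
                       row.names = FALSE)
    }
    results[[task]] <- per_pipe
    if (length(per_pipe) > 1)
      comparisons[[task]] <- compare_models(per_pipe)
  }

  # stage 4: explainability on the first task's fold-1 models
  task1 <- config$tasks[1]
  patterns <- NULL
  top <- NULL
  if ("supervised" %in% config$pipelines) {
    fold_fit <- models_kept[[paste(task1, "supervised", sep = "_")]][[1]]
    covset <- compute_band_covariances(subset_epochs(es, task = task1),
                                       config$cohort$bands, config$shrinkage)
    patterns <- filters_to_patterns(fold_fit$filters, covset)
  }
  if ("handcrafted" %in% config$pipelines) {
    gbm1 <- models_kept[[paste(task1, "handcrafted", sep = "_")]][[1]]
    feats <- relative_power(multitaper_band_power(
      subset_epochs(es, task = task1), config$cohort$bands))
    set.seed(stage_seed(config$seed, "shap"))
    bg_idx <- sample.int(nrow(feats), min(32, nrow(feats)))
    ex_idx <- sample.int(nrow(feats), min(24, nrow(feats)))
    attr <- shap_attributions(gbm1, feats[bg_idx, , drop = FALSE],
                              feats[ex_idx, , drop = FALSE],
                              n_perm = 32,
                              seed = stage_seed(config$seed, "shap_perm"))
    top <- top_features(attr, k = min(config$top_k, ncol(feats)))
    utils::write.csv(top, file.path(config$out_dir, "top_features.csv"),
                     row.names = FALSE)
  }

  report <- structure(list(
    provenance = list(config_hash = hash, seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("bandcov")),
                      n_epochs = n_epochs(es)),
    classification = lapply(results, function(per_pipe)
      lapply(per_pipe, function(r)
        list(mean_ba = r$mean_ba, sd_ba = r$sd_ba,
             mean_auc = r$mean_auc, sd_auc = r$sd_auc,
             folds = r$folds))),
    comparisons = comparisons,
    clusters = cl$clusters,
    top_features = top,
    results = results
  ), class = "run_report")

  jsonlite::write_json(
    list(provenance = report$provenance,
         classification = report$classification,
         comparisons = comparisons,
         clusters = cl$clusters,
         top_features = top),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = 10, dataframe = "rows")
  logf("run complete")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (task in names(x$results)) {
    for (pipe in names(x$results[[task]])) {
      r <- x$results[[task]][[pipe]]
      cat(sprintf("  %-6s %-11s BA %.3f +/- %.3f  AUC %.3f +/- %.3f\n",
                  task, pipe, r$mean_ba, r$sd_ba, r$mean_auc, r$sd_auc))
    }
  }
  if (!is.null(x$top_features)) {
    cat("  top features:", paste(head(x$top_features$feature, 5),
                                 collapse = ", "), "...\n")
  }
  invisible(x)
}
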