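# Internal: fit one covariance-pipeline fold at a fixed J and return the
# fitted transforms + linear model and its validation BA. Only train epochs
# touch the transform fits; only validation epochs steer tuning.
fit_cov_fold <- function(covset, idx_train, idx_val, pipeline, J, C_grid) {
  tr <- subset_covset(covset, idx_train)
  va <- subset_covset(covset, idx_val)
  if (pipeline == "supervised") {
    filters <- csp_fit(tr, labels = tr$group, J = J)
    f_tr <- csp_log_features(tr, filters)
    f_va <- csp_log_features(va, filters)
    refs <- NULL
  } else {
    filters <- pca_fit(tr, J = J)
    refs <- riemann_fit_references(tr, filters)
    f_tr <- riemann_features(tr, filters, refs)
    f_va <- riemann_features(va, filters, refs)
  }
  model <- fit_linear(f_tr, tr$group, f_va, va$group, C_grid = C_grid)
  list(filters = filters, refs = refs, model = model,
       val_ba = balanced_accuracy(va$group,
                                  predict(model, f_va, type = "class")),
       J = J)
}

# Featurize a covset subset with an already-fitted fold.
cov_fold_features <- function(covset, idx, fold_fit, pipeline) {
  sub <- subset_covset(covset, idx)
  if (pipeline == "supervised") csp_log_features(sub, fold_fit$filters)
  else riemann_features(sub, fold_fit$filters, fold_fit$refs)
}

#' Tune the number of spatial components on the validation subjects
#'
#' Fits the requested pipeline at every candidate J on the training epochs
#' and returns the J maximizing validation balanced accuracy; ties are broken
#' toward the smallest J (the most parsimonious projection).
#'
#' @param covset A `band_covariance_set` over all epochs.
#' @param idx_train,idx_val Epoch indices of the training and validation
#'   subjects.
#' @param pipeline `"supervised"` or `"riemannian"`.
#' @param J_candidates Candidate component counts (all `<= N`).
#' @param C_grid Regularization grid for the inner logistic fit.
#' @return A list with `J` (the selected count), `scores` (validation BA per
#'   candidate) and `fit` (the fitted fold at the selected J).
#' @export
tune_components <- function(covset, idx_train, idx_val,
                            pipeline = c("supervised", "riemannian"),
                            J_candidates = c(2, 4, 6),
                            C_grid = default_C_grid()) {
  pipeline <- match.arg(pipeline)
  N <- length(covset$ch_names)
  if (any(J_candidates < 1) || any(J_candidates > N))
    stop_invalid("J candidates must lie in [1, ", N, "]")
  J_candidates <- sort(unique(J_candidates))
  fits <- lapply(J_candidates, function(J)
    fit_cov_fold(covset, idx_train, idx_val, pipeline, J, C_grid))
  scores <- vapply(fits, function(f) f$val_ba, 0)
  best <- which.max(scores)  # candidates ascending: first max = smallest J
  list(J = J_candidates[best],
       scores = stats::setNames(scores, J_candidates),
       fit = fits[[best]])
}

#' Evaluate a decoding pipeline with leave-subjects-out folds
#'
#' Runs the full subject-independent evaluation: per fold, all feature
#' transforms and classifiers are fitted on the training subjects' epochs
#' only, the component count / hyperparameters are tuned on the validation
#' subjects, and the held-out test subjects' epochs are scored once. Reports
#' per-fold balanced accuracy and AUC plus their mean and SD.
#'
#' Pipelines: `"supervised"` (per-band CSP + log-variance features + L2
#' logistic regression), `"riemannian"` (per-band PCA + tangent-space
#' vectorization + L2 logistic regression), `"handcrafted"` (multitaper
#' relative band power + gradient-boosted trees).
#'
#' @param epochs An `epoch_set`.
#' @param pipeline One of `"supervised"`, `"riemannian"`, `"handcrafted"`.
#' @param plan A `fold_plan` over the subjects present in `epochs`.
#' @param task Optional task label to restrict to (tasks are classified
#'   separately by default elsewhere; here `NULL` uses all epochs given).
#' @param bands Band table.
#' @param J_candidates Component counts tuned per fold (covariance pipelines).
#' @param shrinkage Covariance shrinkage fraction.
#' @param C_grid Logistic regularization grid.
#' @param gbm_grid Boosted-tree hyperparameter grid.
#' @param nrounds,early_stopping Boosting limits.
#' @param nw,n_tapers Multitaper settings (handcrafted pipeline).
#' @param seed Base seed (per-fold tree seeds are derived from it).
#' @param keep_models Keep per-fold fitted models (for explainability).
#' @return An object of class `classification_result` with `folds` (data
#'   frame: ba, auc, J, tuned hyperparameters), `mean_ba`, `sd_ba`,
#'   `mean_auc`, `sd_auc`, `pipeline`, `task`.
#' @export
evaluate_pipeline <- function(epochs,
                              pipeline = c("supervised", "riemannian",
                                           "handcrafted"),
                              plan, task = NULL,
                              bands = default_bands(),
                              J_candidates = c(2, 4, 6),
                              shrinkage = 0.05,
                              C_grid = default_C_grid(),
                              gbm_grid = gbm_default_grid(),
                              nrounds = 150, early_stopping = 15,
                              nw = 2, n_tapers = 3,
                              seed = 1L, keep_models = FALSE) {
  pipeline <- match.arg(pipeline)
  stopifnot(inherits(plan, "fold_plan"))
  if (!is.null(task)) epochs <- subset_epochs(epochs, task = task)
  if (n_epochs(epochs) == 0) stop("no epochs to evaluate", call. = FALSE)
  subj <- epochs$subject

  plan_subjects <- unique(unlist(lapply(plan$folds, unlist)))
  if (!all(plan_subjects %in% subj))
    stop("fold plan references subjects absent from the epochs: ",
         paste(setdiff(plan_subjects, subj), collapse = ", "), call. = FALSE)

  # Per-epoch transforms are fitting-free, so they are computed once.
  if (pipeline %in% c("supervised", "riemannian")) {
    covset <- compute_band_covariances(epochs, bands, shrinkage)
  } else {
    feats <- relative_power(multitaper_band_power(epochs, bands, nw, n_tapers))
  }

  rows <- vector("list", length(plan$folds))
  models <- if (keep_models) vector("list", length(plan$folds)) else NULL
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    assert_fold_disjoint(fold)
    idx_train <- which(subj %in% fold$train)
    idx_val <- which(subj %in% fold$validation)
    idx_test <- which(subj %in% fold$test)
    if (length(intersect(idx_test, c(idx_train, idx_val))) > 0)
      stop("leakage guard: test epochs overlap fitting epochs", call. = FALSE)

    if (pipeline == "handcrafted") {
      model <- fit_gbm(feats[idx_train, , drop = FALSE], epochs$group[idx_train],
                       feats[idx_val, , drop = FALSE], epochs$group[idx_val],
                       grid = gbm_grid, nrounds = nrounds,
                       early_stopping = early_stopping,
                       seed = as.integer(seed) + f)
      scores <- predict(model, feats[idx_test, , drop = FALSE], type = "score")
      pred <- ifelse(scores > 0.5, model$levels[2], model$levels[1])
      Jsel <- NA_integer_
      hp <- sprintf("eta=%g,leaves=%d,mcw=%g", model$best_params$eta,
                    model$best_params$max_leaves,
                    model$best_params$min_child_weight)
    } else {
      tuned <- tune_components(covset, idx_train, idx_val, pipeline,
                               J_candidates, C_grid)
      model <- tuned$fit$model
      f_te <- cov_fold_features(covset, idx_test, tuned$fit, pipeline)
      scores <- predict(model, f_te, type = "score")
      pred <- predict(model, f_te, type = "class")
      Jsel <- tuned$J
      hp <- sprintf("C=%.3g", model$C)
      if (keep_models) model <- tuned$fit  # transforms + linear model
    }
    y_te <- epochs$group[idx_test]
    rows[[f]] <- data.frame(
      fold = f,
      ba = balanced_accuracy(y_te, pred),
      auc = roc_auc(y_te, scores),
      J = Jsel, hyperparameters = hp,
      stringsAsFactors = FALSE)
    if (keep_models) models[[f]] <- model
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 mean_ba = mean(folds$ba), sd_ba = sd(folds$ba),
                 mean_auc = mean(folds$auc), sd_auc = sd(folds$auc),
                 pipeline = pipeline, task = task %||% "all",
                 seed = as.integer(seed), models = models),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> pipeline %s, task %s (%d folds)\n",
              x$pipeline, x$task, nrow(x$folds)))
  cat(sprintf("  BA  %.3f +/- %.3f\n", x$mean_ba, x$sd_ba))
  cat(sprintf("  AUC %.3f +/- %.3f\n", x$mean_auc, x$sd_auc))
  invisible(x)
}
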