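#' Default regularization grid for the logistic pipeline
#'
#' 20 log-spaced inverse-regularization values C spanning `[1e-10, 1e9]`;
#' larger C = weaker L2 penalty.
#'
#' @return Numeric vector of C values, increasing.
#' @export
default_C_grid <- function() 10^seq(-10, 9, length.out = 20)

#' Fit an L2-regularized logistic regression with validation-based tuning
#'
#' Fits the full ridge-logistic path over the C grid (via glmnet with
#' `lambda = 1 / (n * C)`) on the training epochs and retains the C value
#' that maximizes balanced accuracy on the validation epochs. Ties are broken
#' toward stronger regularization. The weight vector at the selected C is
#' kept for activation-pattern analysis.
#'
#' For linearly separable training data the weakest penalties have no finite
#' optimum; glmnet then returns the converged part of the path and selection
#' proceeds over those grid points (the number retained is recorded in
#' `n_converged`).
#'
#' @param x Training feature matrix (epochs x features).
#' @param y Training labels (2 classes).
#' @param x_val,y_val Validation epochs used only for selecting C.
#' @param C_grid Inverse-regularization grid (default [default_C_grid()]).
#' @return An object of class `bandcov_linear`: the fitted model, selected
#'   `C` / `lambda`, weights `w`, `intercept`, class levels, and the
#'   validation BA per grid point.
#' @export
fit_linear <- function(x, y, x_val, y_val, C_grid = default_C_grid()) {
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  y <- as.character(y); y_val <- as.character(y_val)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("training labels must have two classes",
                             call. = FALSE)
  if (length(unique(y_val)) < 2)
    stop("validation set is single-class; cannot tune", call. = FALSE)
  if (length(C_grid) == 0) stop_invalid("C grid is empty")
  n <- nrow(x)
  lam <- sort(1 / (n * C_grid), decreasing = TRUE)  # strongest penalty first
  yf <- factor(y, levels = lev)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, yf, family = "binomial", alpha = 0, lambda = lam,
                   standardize = TRUE, thresh = 1e-12),
    warning = function(w) {
      # separable data: the unpenalized end of the path has no finite
      # optimum; glmnet returns the converged prefix, which is what we use
      if (grepl("Convergence for .* lambda value not reached",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pv <- predict(fit, x_val, type = "response")      # P(level 2) per lambda
  ba <- apply(pv, 2, function(p) {
    balanced_accuracy(y_val, ifelse(p > 0.5, lev[2], lev[1]))
  })
  best <- which.max(ba)  # lambdas decreasing: first max = strongest penalty
  lambda <- fit$lambda[best]
  w <- as.numeric(fit$beta[, best])
  names(w) <- colnames(x)
  structure(list(fit = fit, lambda = lambda, C = 1 / (n * lambda),
                 lambda_index = best, w = w,
                 intercept = unname(fit$a0[best]),
                 levels = lev, positive = lev[2],
                 n_converged = length(fit$lambda),
                 val_ba = stats::setNames(ba, signif(fit$lambda, 3))),
            class = "bandcov_linear")
}

#' @export
predict.bandcov_linear <- function(object, newdata,
                                   type = c("score", "class"), ...) {
  type <- match.arg(type)
  p <- predict(object$fit, as.matrix(newdata), type = "response")[,
               object$lambda_index]
  if (type == "score") p
  else ifelse(p > 0.5, object$levels[2], object$levels[1])
}

#' @export
print.bandcov_linear <- function(x, ...) {
  cat(sprintf("<bandcov_linear> L2 logistic regression, C = %.3g (%d features)\n",
              x$C, length(x$w)))
  invisible(x)
}

#' Default hyperparameter grid for the gradient-boosted pipeline
#'
#' A 3 x 3 x 3 grid over learning rate, leaf count and minimum child weight,
#' a desk-scale reduction of the usual boosted-tree search space.
#'
#' @return A data frame of grid points.
#' @export
gbm_default_grid <- function() {
  expand.grid(eta = c(0.05, 0.1, 0.3),
              max_leaves = c(7, 15, 31),
              min_child_weight = c(5, 10, 20))
}

#' Fit a gradient-boosted tree ensemble with validation-based grid search
#'
#' Trains leaf-wise-grown boosted trees (xgboost, `grow_policy = "lossguide"`)
#' for every grid point, with early stopping on validation log-loss, and
#' retains the configuration with the best validation balanced accuracy
#' (ties: first grid row). Deterministic given `seed` (single-threaded).
#'
#' @param x Training feature matrix.
#' @param y Training labels (2 classes).
#' @param x_val,y_val Validation epochs (tuning and early stopping only).
#' @param grid Data frame with columns `eta`, `max_leaves`,
#'   `min_child_weight` (default [gbm_default_grid()]).
#' @param nrounds Maximum boosting rounds (default 150).
#' @param early_stopping Early-stopping patience in rounds (default 15).
#' @param seed Integer seed for the tree construction.
#' @return An object of class `bandcov_gbm`.
#' @export
fit_gbm <- function(x, y, x_val, y_val, grid = gbm_default_grid(),
                    nrounds = 150, early_stopping = 15, seed = 1L) {
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  y <- as.character(y); y_val <- as.character(y_val)
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("training labels must have two classes",
                             call. = FALSE)
  if (is.null(grid) || nrow(grid) == 0) stop_invalid("hyperparameter grid is empty")
  feat_names <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  colnames(x) <- feat_names
  colnames(x_val) <- feat_names
  dtr <- xgboost::xgb.DMatrix(x, label = as.integer(y == lev[2]))
  dva <- xgboost::xgb.DMatrix(x_val, label = as.integer(y_val == lev[2]))
  best <- NULL
  for (gi in seq_len(nrow(grid))) {
    params <- list(objective = "binary:logistic",
                   eta = grid$eta[gi],
                   grow_policy = "lossguide", max_depth = 0,
                   max_leaves = grid$max_leaves[gi],
                   min_child_weight = grid$min_child_weight[gi],
                   tree_method = "hist", nthread = 1,
                   seed = as.integer(seed))
    bst <- xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                              evals = list(val = dva),
                              early_stopping_rounds = early_stopping,
                              verbose = 0)
    pv <- predict(bst, dva)
    ba <- balanced_accuracy(y_val, ifelse(pv > 0.5, lev[2], lev[1]))
    if (is.null(best) || ba > best$ba) {
      best <- list(booster = bst, ba = ba, params = grid[gi, , drop = FALSE],
                   best_iteration =
                     as.integer(xgboost::xgb.attr(bst, "best_iteration")))
    }
  }
  structure(list(booster = best$booster, best_params = best$params,
                 best_iteration = best$best_iteration, val_ba = best$ba,
                 levels = lev, positive = lev[2],
                 feature_names = feat_names, seed = as.integer(seed)),
            class = "bandcov_gbm")
}

#' @export
predict.bandcov_gbm <- function(object, newdata,
                                type = c("score", "class", "margin"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    stop("feature names of `newdata` do not match the model", call. = FALSE)
  colnames(newdata) <- object$feature_names
  dm <- xgboost::xgb.DMatrix(newdata)
  if (type == "margin") return(predict(object$booster, dm, outputmargin = TRUE))
  p <- predict(object$booster, dm)
  if (type == "score") p
  else ifelse(p > 0.5, object$levels[2], object$levels[1])
}

#' @export
print.bandcov_gbm <- function(x, ...) {
  cat(sprintf("<bandcov_gbm> boosted trees (eta=%g, leaves=%d, min_child=%g), val BA %.3f\n",
              x$best_params$eta, x$best_params$max_leaves,
              x$best_params$min_child_weight, x$val_ba))
  invisible(x)
}

#' Split-gain feature importance of a fitted boosted ensemble
#'
#' @param model A `bandcov_gbm`.
#' @return Data frame with `feature` and `gain`, sorted decreasing.
#' @export
gbm_importance <- function(model) {
  stopifnot(inherits(model, "bandcov_gbm"))
  imp <- xgboost::xgb.importance(model = model$booster)
  data.frame(feature = imp$Feature, gain = imp$Gain)
}
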