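#' Shapley-value feature attributions for a fitted model
#'
#' Computes additive per-feature attributions of the model output for each
#' explained epoch under the interventional (background-marginalized) value
#' function: the value of a feature coalition S is the mean model output
#' over the background sample with the features in S replaced by the
#' explained epoch's values. For tree ensembles the output is explained in
#' margin (log-odds) space, where the attributions are additive.
#'
#' With at most `max_exact` features the exact Shapley value is computed by
#' full coalition enumeration; above that a seeded antithetic
#' permutation-sampling estimator is used. Both satisfy local accuracy:
#' `base_value + rowSums(values)` equals the model output for every explained
#' epoch (asserted to 1e-6).
#'
#' @param model A `bandcov_gbm`, or any function mapping a feature matrix to
#'   a numeric output vector.
#' @param x_background Background feature matrix (marginalization sample).
#' @param x_explain Epochs to explain.
#' @param max_exact Feature-count threshold for exact enumeration (default
#'   10).
#' @param n_perm Number of sampled permutations (sampling mode; default 64,
#'   rounded up to even for antithetic pairing).
#' @param seed Seed for the permutation sampler.
#' @return An object of class `attribution_matrix`: list with `values`
#'   (epochs x features), `base_value`, `feature_names`, `method`.
#' @export
shap_attributions <- function(model, x_background, x_explain,
                              max_exact = 10, n_perm = 64, seed = 1L) {
  x_background <- as.matrix(x_background)
  x_explain <- as.matrix(x_explain)
  if (nrow(x_background) == 0) stop_invalid("background sample is empty")
  if (ncol(x_background) != ncol(x_explain))
    stop_invalid("background and explained epochs have different feature counts")
  if (inherits(model, "bandcov_gbm")) {
    fn <- model$feature_names
    bn <- colnames(x_background) %||% fn
    en <- colnames(x_explain) %||% fn
    if (!identical(bn, fn) || !identical(en, fn))
      stop("feature names do not match the model", call. = FALSE)
    colnames(x_background) <- fn
    colnames(x_explain) <- fn
    f <- function(x) {
      colnames(x) <- fn
      predict(model, x, type = "margin")
    }
  } else if (is.function(model)) {
    f <- model
  } else stop_invalid("`model` must be a bandcov_gbm or a prediction function")

  p <- ncol(x_explain)
  feature_names <- colnames(x_explain) %||% paste0("f", seq_len(p))
  if (p <= max_exact) {
    res <- shap_exact(f, x_background, x_explain)
    method <- "exact"
  } else {
    res <- shap_sampling(f, x_background, x_explain, n_perm, seed)
    method <- "sampling"
  }
  fx <- f(x_explain)
  err <- max(abs(res$base + rowSums(res$values) - fx))
  if (err > 1e-6)
    stop("local accuracy violated (max error ", format(err), ")", call. = FALSE)
  structure(list(values = res$values, base_value = res$base,
                 feature_names = feature_names, method = method),
            class = "attribution_matrix")
}

# Exact Shapley values by full coalition enumeration. v(S) is evaluated for
# all 2^p subsets in one batched model call per explained epoch.
shap_exact <- function(f, bg, xe) {
  p <- ncol(xe)
  nb <- nrow(bg)
  n_sub <- 2^p
  subsets <- lapply(0:(n_sub - 1),
                    function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  sizes <- lengths(subsets)
  # w(|S|); the full coalition never appears as an "S without j" so its
  # weight is unused (set to 0 rather than evaluating factorial(-1))
  wt <- ifelse(sizes < p,
               factorial(sizes) * factorial(pmax(p - sizes - 1, 0)) /
                 factorial(p),
               0)
  phi <- matrix(0, nrow(xe), p)
  base <- NA_real_
  for (i in seq_len(nrow(xe))) {
    big <- bg[rep(seq_len(nb), n_sub), , drop = FALSE]
    for (m in seq_len(n_sub)) {
      S <- subsets[[m]]
      if (length(S) > 0) {
        rows <- (m - 1) * nb + seq_len(nb)
        big[rows, S] <- matrix(xe[i, S], nb, length(S), byrow = TRUE)
      }
    }
    colnames(big) <- colnames(xe)
    v <- colMeans(matrix(f(big), nb, n_sub))
    base <- v[1]  # empty coalition
    for (j in seq_len(p)) {
      bit <- 2^(j - 1)
      without <- which(bitwAnd(0:(n_sub - 1), bit) == 0)
      phi[i, j] <- sum(wt[without] * (v[without + bit] - v[without]))
    }
  }
  colnames(phi) <- colnames(xe)
  list(values = phi, base = base)
}

# Antithetic permutation-sampling Shapley estimator. Each permutation's
# marginal contributions telescope exactly to f(x) - E[f(background)], so
# local accuracy holds for the average as well.
shap_sampling <- function(f, bg, xe, n_perm, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  p <- ncol(xe)
  nb <- nrow(bg)
  half <- ceiling(n_perm / 2)
  perms <- vector("list", 2 * half)
  for (h in seq_len(half)) {
    pr <- sample.int(p)
    perms[[2 * h - 1]] <- pr
    perms[[2 * h]] <- rev(pr)
  }
  base <- mean(f(bg))
  phi <- matrix(0, nrow(xe), p)
  for (i in seq_len(nrow(xe))) {
    acc <- numeric(p)
    for (pr in perms) {
      # rows k = 0..p: background with features pr[seq_len(k)] set to x_i
      big <- bg[rep(seq_len(nb), p + 1), , drop = FALSE]
      xi <- xe[i, ]
      for (k in seq_len(p)) {
        rows <- k * nb + seq_len(nb)
        cols <- pr[seq_len(k)]
        big[rows, cols] <- matrix(xi[cols], nb, k, byrow = TRUE)
      }
      colnames(big) <- colnames(xe)
      v <- colMeans(matrix(f(big), nb, p + 1))
      acc[pr] <- acc[pr] + diff(v)
    }
    phi[i, ] <- acc / length(perms)
  }
  colnames(phi) <- colnames(xe)
  list(values = phi, base = base)
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> %d epochs x %d features (%s), base %.4f\n",
              nrow(x$values), ncol(x$values), x$method, x$base_value))
  invisible(x)
}

#' Rank features by mean absolute attribution
#'
#' @param attr An `attribution_matrix`.
#' @param k Number of features to return (default 10).
#' @return Data frame `feature`, `mean_abs_attribution`, sorted decreasing
#'   (ties broken by feature name, stable).
#' @export
top_features <- function(attr, k = 10) {
  stopifnot(inherits(attr, "attribution_matrix"))
  if (k > length(attr$feature_names))
    stop_invalid("k exceeds the number of features")
  imp <- colMeans(abs(attr$values))
  ord <- order(-imp, attr$feature_names)
  data.frame(feature = attr$feature_names[ord],
             mean_abs_attribution = unname(imp[ord]))[seq_len(k), ]
}
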