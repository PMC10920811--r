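#' Balanced accuracy
#'
#' Mean of sensitivity and specificity: for binary labels,
#' `(TP/(TP+FN) + TN/(TN+FP)) / 2`. Chance level is 0.5 regardless of class
#' imbalance.
#'
#' @param y_true True binary labels.
#' @param y_pred Predicted labels on the same label set.
#' @return Balanced accuracy in \[0, 1\].
#' @export
#' @examples
#' balanced_accuracy(rep(c("M", "H"), c(10, 10)),
#'                   rep(c("M", "H", "M", "H"), c(8, 2, 4, 6)))  # 0.7
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  cls <- sort(unique(y_true))
  if (length(cls) != 2)
    stop("balanced accuracy requires both classes in y_true", call. = FALSE)
  rec <- vapply(cls, function(cl) mean(y_pred[y_true == cl] == cl), 0)
  mean(rec)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' epoch receives a higher score than a randomly chosen negative one, ties
#' counted one half.
#'
#' @param y_true True binary labels.
#' @param scores Real-valued scores, higher = more positive.
#' @param positive The positive class (default: the lexicographically larger
#'   label, so `"M"` for M/H groups).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores, positive = NULL) {
  y_true <- as.character(y_true)
  cls <- sort(unique(y_true))
  if (length(cls) != 2)
    stop("AUC requires both classes in y_true", call. = FALSE)
  positive <- positive %||% cls[2]
  pos <- y_true == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise model comparison on per-fold balanced accuracy
#'
#' Two-sided Wilcoxon signed-rank tests on the fold-paired balanced
#' accuracies of every pair of classification results. Results must come
#' from the same fold plan (equal fold counts, paired by fold). When two
#' models have identical per-fold BA the difference vector is all zero and
#' the p-value is defined as 1 (no evidence of a difference).
#'
#' @param results Named list of `classification_result` objects.
#' @return Data frame with columns `model1`, `model2`, `statistic` and
#'   `p_value`.
#' @export
compare_models <- function(results) {
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- vapply(results, function(r) r$pipeline, "")
  nf <- vapply(results, function(r) nrow(r$folds), 0L)
  if (length(unique(nf)) != 1)
    stop("results are not paired: unequal fold counts", call. = FALSE)
  cmb <- combn(names(results), 2)
  rows <- apply(cmb, 2, function(pr) {
    x <- results[[pr[1]]]$folds$ba
    y <- results[[pr[2]]]$folds$ba
    st <- signed_rank_test(x, y)
    data.frame(model1 = pr[1], model2 = pr[2],
               statistic = st$statistic, p_value = st$p_value)
  })
  do.call(rbind, rows)
}

# Two-sided Wilcoxon signed-rank test. Zero differences are dropped (all
# zero -> p = 1 by convention). For n <= 14 retained differences the exact
# sign-flip distribution of V is enumerated (valid with tied |d|, where
# stats::wilcox.test must approximate); larger n uses wilcox.test.
signed_rank_test <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 14) {
    vals <- vapply(0:(2^n - 1), function(m) {
      sum(r[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
    }, 0)
    p <- min(1, 2 * min(mean(vals <= v), mean(vals >= v)))
  } else {
    p <- suppressWarnings(wilcox.test(d)$p.value)
  }
  list(statistic = v, p_value = p)
}
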