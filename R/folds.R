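#' Build leave-subjects-out folds with validation subjects
#'
#' Each fold holds out one test subject per group and one validation subject
#' per group (for hyperparameter / component tuning); the remaining subjects
#' train the models. Test pairs are drawn without replacement across folds
#' while distinct pairs remain, then with replacement (reported via a
#' message). All epochs of a held-out subject are excluded from fitting, so
#' performance measures cross-person generalization.
#'
#' @param subjects Character vector of unique subject ids.
#' @param groups Group label per subject (exactly 2 groups, >= 3 subjects
#'   each).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return An object of class `fold_plan`: list of folds, each with `train`,
#'   `validation` and `test` subject vectors.
#' @export
make_folds <- function(subjects, groups, n_folds = 10, seed = 1L) {
  subjects <- as.character(subjects)
  groups <- as.character(groups)
  if (anyDuplicated(subjects)) stop_invalid("subject ids must be unique")
  if (length(groups) != length(subjects))
    stop_invalid("`groups` must have one entry per subject")
  gl <- sort(unique(groups))
  if (length(gl) != 2) stop_invalid("exactly two groups are required")
  g1 <- subjects[groups == gl[1]]
  g2 <- subjects[groups == gl[2]]
  if (length(g1) < 3 || length(g2) < 3)
    stop("need at least 3 subjects per group to fill train/validation/test",
         call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  pairs <- expand.grid(a = g1, b = g2, stringsAsFactors = FALSE)
  if (nrow(pairs) >= n_folds) {
    sel <- pairs[sample.int(nrow(pairs), n_folds), , drop = FALSE]
  } else {
    message("fewer distinct test pairs (", nrow(pairs), ") than folds (",
            n_folds, "); sampling test pairs with replacement")
    sel <- pairs[sample.int(nrow(pairs), n_folds, replace = TRUE), ,
                 drop = FALSE]
  }
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- c(sel$a[f], sel$b[f])
    rem1 <- setdiff(g1, test)
    rem2 <- setdiff(g2, test)
    validation <- c(rem1[sample.int(length(rem1), 1)],
                    rem2[sample.int(length(rem2), 1)])
    train <- setdiff(subjects, c(test, validation))
    fold <- list(train = train, validation = validation, test = test)
    assert_fold_disjoint(fold)
    fold
  })
  structure(list(folds = folds, seed = as.integer(seed),
                 groups = stats::setNames(groups, subjects)),
            class = "fold_plan")
}

# Leakage guard: the three roles of a fold must not share subjects.
assert_fold_disjoint <- function(fold) {
  all_s <- c(fold$train, fold$validation, fold$test)
  if (anyDuplicated(all_s))
    stop("fold roles are not subject-disjoint: ",
         paste(unique(all_s[duplicated(all_s)]), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds (seed %d)\n", length(x$folds), x$seed))
  for (f in seq_along(x$folds)) {
    fd <- x$folds[[f]]
    cat(sprintf("  fold %2d: test {%s} val {%s} train n=%d\n", f,
                paste(fd$test, collapse = ","),
                paste(fd$validation, collapse = ","), length(fd$train)))
  }
  invisible(x)
}
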