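make_toy <- function(n = 120, seed = 1, sep = 3) {
  set.seed(seed)
  y <- rep(c("M", "H"), each = n / 2)
  x <- matrix(rnorm(n * 2), n, 2)
  x[y == "M", 1] <- x[y == "M", 1] + sep
  colnames(x) <- c("f1", "f2")
  list(x = x, y = y)
}

test_that("ridge logistic separates a separable toy and shrinks under heavy penalty", {
  # linearly separable classes with a clear margin
  set.seed(1)
  y <- rep(c("M", "H"), each = 60)
  x <- cbind(f1 = c(runif(60, 1, 2), runif(60, -2, -1)), f2 = rnorm(120))
  # near-unpenalized logistic on separable data has no finite optimum, so
  # glmnet may flag non-convergence at the weakest penalties; expected here
  m <- suppressWarnings(fit_linear(x, y, x, y, C_grid = 1e3))
  expect_equal(balanced_accuracy(y, predict(m, x, type = "class")), 1.0)
  tr <- make_toy(seed = 1)
  va <- make_toy(seed = 2)
  # extreme penalty only: weights collapse toward zero, scores toward 0.5
  m_hi <- suppressWarnings(fit_linear(tr$x, tr$y, va$x, va$y, C_grid = 1e-10))
  expect_lt(max(abs(m_hi$w)), 1e-4)
  expect_equal(predict(m_hi, tr$x, type = "score"), rep(0.5, 120),
               tolerance = 0.01)
})

test_that("mirrored feature pairs receive symmetric ridge weights", {
  tr <- make_toy(seed = 3)
  va <- make_toy(seed = 4)
  xm <- cbind(tr$x[, 1], -tr$x[, 1])  # exactly mirrored predictors
  colnames(xm) <- c("p", "m")
  vm <- cbind(va$x[, 1], -va$x[, 1])
  colnames(vm) <- c("p", "m")
  m <- suppressWarnings(fit_linear(xm, tr$y, vm, va$y, C_grid = c(0.1, 1)))
  expect_equal(abs(m$w[["p"]]), abs(m$w[["m"]]), tolerance = 1e-6)
  expect_error(fit_linear(tr$x, tr$y, va$x, rep("M", 120)), "single-class")
})

test_that("boosted trees credit the only informative feature and are deterministic", {
  set.seed(5)
  n <- 300
  y <- sample(c("M", "H"), n, replace = TRUE)
  x <- cbind(info = as.integer(y == "M"), noise1 = rnorm(n), noise2 = rnorm(n))
  va_idx <- 251:300
  m <- fit_gbm(x[-va_idx, ], y[-va_idx], x[va_idx, ], y[va_idx],
               grid = gbm_default_grid()[1:2, ], seed = 9)
  imp <- gbm_importance(m)
  expect_equal(imp$feature[1], "info")
  expect_gt(imp$gain[1], 0.9)
  m2 <- fit_gbm(x[-va_idx, ], y[-va_idx], x[va_idx, ], y[va_idx],
                grid = gbm_default_grid()[1:2, ], seed = 9)
  expect_identical(predict(m, x, type = "score"), predict(m2, x, type = "score"))
  expect_error(fit_gbm(x[-va_idx, ], y[-va_idx], x[va_idx, ], y[va_idx],
                       grid = gbm_default_grid()[0, ]), "grid")
  # mismatched feature names are refused at prediction time
  xbad <- x; colnames(xbad) <- c("a", "b", "c")
  expect_error(predict(m, xbad), "feature names")
})

test_that("label-shuffled training yields chance-level held-out BA", {
  set.seed(11)
  n <- 200
  x <- matrix(rnorm(n * 4), n, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c("M", "H"), n / 2)
  bas <- sapply(1:20, function(s) {
    set.seed(s)
    ysh <- sample(y[1:120])
    m <- fit_gbm(x[1:120, ], ysh, x[121:160, ], y[121:160],
                 grid = gbm_default_grid()[1, ], nrounds = 40, seed = s)
    balanced_accuracy(y[161:200], predict(m, x[161:200, ], type = "class"))
  })
  expect_lt(abs(mean(bas) - 0.5), 0.1)
})

test_that("component tuning maximizes validation BA with smallest-J ties", {
  coh <- generate_cohort(small_cohort(seed = 6, ratio = 3, n_subj = 4,
                                      n_ch = 8, n_ep = 8))
  covset <- compute_band_covariances(coh$epochs)
  subj <- coh$epochs$subject
  idx_train <- which(subj %in% sprintf("S%02d", c(1, 2, 5, 6)))
  idx_val <- which(subj %in% sprintf("S%02d", c(3, 7)))
  # single candidate comes back unchanged
  t1 <- tune_components(covset, idx_train, idx_val, "supervised",
                        J_candidates = 4)
  expect_equal(t1$J, 4)
  expect_error(tune_components(covset, idx_train, idx_val, "supervised",
                               J_candidates = c(2, 99)), "candidates")
  # all-equal scores break toward the smallest J (forced by identical folds)
  t2 <- tune_components(covset, idx_train, idx_val, "supervised",
                        J_candidates = c(2, 2))
  expect_equal(t2$J, 2)
})

test_that("planted single-source effect tunes to a small component count", {
  hits <- sapply(1:5, function(s) {
    coh <- generate_cohort(small_cohort(seed = 40 + s, ratio = 4, n_subj = 4,
                                        n_ch = 10, n_ep = 8, noise_sd = 0.3,
                                        subject_sd = 0.1))
    covset <- compute_band_covariances(coh$epochs)
    subj <- coh$epochs$subject
    idx_train <- which(subj %in% sprintf("S%02d", c(1, 2, 5, 6)))
    idx_val <- which(subj %in% sprintf("S%02d", c(3, 7)))
    tn <- tune_components(covset, idx_train, idx_val, "supervised",
                          J_candidates = c(1, 2, 3, 4, 6, 8))
    tn$J
  })
  expect_gte(mean(hits <= 3), 0.8)
})
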