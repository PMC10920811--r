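test_that("epoch extraction yields non-overlapping 2-s windows after the offset", {
  fs <- 250
  x <- matrix(rnorm(2 * 20 * fs), nrow = 2)  # 20 s, 2 channels
  es <- extract_epochs(x, fs, onsets = 0, subject = "S1", group = "M",
                       task = "verb", trial_ends = 14)  # 9 s usable
  expect_equal(n_epochs(es), 4)                 # floor(9 / 2)
  expect_equal(dim(es$data)[3], 500)            # 2 s x 250 Hz
  expect_equal(unique(es$task), "verb")
  # epochs tile the signal: epoch 2 starts where epoch 1 ends
  s0 <- round((0 + 5) * fs)
  expect_equal(es$data[2, 1, ], x[1, (s0 + 501):(s0 + 1000)])
})

test_that("epoching handles empty input and out-of-range onsets", {
  fs <- 100
  x <- matrix(rnorm(300), nrow = 1)  # 3 s
  es <- extract_epochs(x, fs, onsets = numeric(0), subject = character(0),
                       group = character(0), task = character(0))
  expect_equal(n_epochs(es), 0)
  expect_warning(
    es2 <- extract_epochs(x, fs, onsets = 0, subject = "S1", group = "M",
                          task = "t"),
    "skipped")
  expect_equal(n_epochs(es2), 0)
})

test_that("peak-to-peak rejection keeps epochs within bounds only", {
  arr <- array(0, dim = c(3, 2, 100))
  arr[1, , ] <- matrix(sin(seq_len(100) / 5), 2, 100, byrow = TRUE) * 10  # ptp 20
  arr[2, , ] <- arr[1, , ]
  arr[2, 1, 50] <- 500                                 # single-channel spike
  # epoch 3 stays all-zero: flat, below ptp_min
  es <- epoch_set(arr, 100, c("a", "b"), subject = rep("S", 3),
                  group = rep("M", 3), task = rep("t", 3))
  rj <- reject_epochs(es, ptp_min = 1, ptp_max = 150)
  expect_equal(rj$kept, c(TRUE, FALSE, FALSE))
  expect_equal(n_epochs(rj$epochs), 1)
  all_in <- reject_epochs(es, ptp_min = 0, ptp_max = Inf)
  expect_true(all(all_in$kept))
  expect_error(reject_epochs(es, 10, 12), "rejected")
  expect_error(reject_epochs(es, 5, 5), "ptp_min")
})

test_that("filter bank passes in-band sinusoids and rejects out-of-band", {
  # steady-state gains need epochs much longer than the filter transient
  fs <- 250
  t <- seq_len(4000) / fs
  x <- cbind(sin(2 * pi * 9 * t))       # inside alpha1 (8-10 Hz)
  es <- epochs_from_matrix(x, fs = fs)
  be <- apply_filter_bank(es)
  v_in <- var(x[, 1])
  v_alpha1 <- var(be$data[3, 1, 1, ])
  v_beta3 <- var(be$data[7, 1, 1, ])
  expect_gt(v_alpha1, 0.9 * v_in)
  expect_lt(v_beta3, 0.01 * v_in)
  # band-edge frequency: zero-phase power gain equals |H|^4 of an
  # independently designed transfer-function filter
  x10 <- cbind(sin(2 * pi * 10 * t))
  be10 <- apply_filter_bank(epochs_from_matrix(x10, fs = fs))
  bt <- signal::butter(4, c(8, 10) / (fs / 2), type = "pass")
  g <- filter_gain(bt, 10, fs)
  expect_equal(var(be10$data[3, 1, 1, ]) / var(x10[, 1]), g^4,
               tolerance = 0.05)
  # band edges at/above Nyquist are refused
  bad <- default_bands()
  bad$high[7] <- 130
  expect_error(apply_filter_bank(es, bands = bad), "Nyquist")
})

test_that("filter bank is linear and maps zero to zero", {
  set.seed(1)
  x <- matrix(rnorm(500 * 2), 500, 2)
  es_x <- epochs_from_matrix(x[, 1, drop = FALSE])
  es_y <- epochs_from_matrix(x[, 2, drop = FALSE])
  es_lin <- epochs_from_matrix(cbind(2 * x[, 1] - 3 * x[, 2]))
  bx <- apply_filter_bank(es_x)$data
  by <- apply_filter_bank(es_y)$data
  bl <- apply_filter_bank(es_lin)$data
  expect_lt(max(abs(bl - (2 * bx - 3 * by))), 1e-10)
  zero <- apply_filter_bank(epochs_from_matrix(cbind(rep(0, 500))))
  expect_equal(max(abs(zero$data)), 0)
})

test_that("white-noise band variances scale with the filters' energy", {
  fs <- 250
  set.seed(42)
  x <- matrix(rnorm(8000 * 60), 8000, 60)   # long epochs: steady state
  es <- epochs_from_matrix(x, fs = fs)
  be <- apply_filter_bank(es)
  v_emp <- sapply(1:7, function(k) mean(apply(be$data[k, , 1, ], 1, var)))
  # oracle: integrate the zero-phase power response |H|^4 over frequency
  bands <- default_bands()
  fgrid <- seq(0.1, fs / 2 - 0.1, by = 0.05)
  v_th <- sapply(1:7, function(k) {
    bt <- signal::butter(4, c(bands$low[k], bands$high[k]) / (fs / 2), "pass")
    g <- sapply(fgrid, filter_gain, bt = bt, fs = fs)
    2 * sum(g^4) * 0.05 / fs
  })
  expect_equal(v_emp / v_th, rep(1, 7), tolerance = 0.1)
})

test_that("multitaper band power matches flat- and line-spectrum oracles", {
  fs <- 250
  # zero signal -> zero power
  z <- multitaper_band_power(epochs_from_matrix(cbind(rep(0, 500)), fs))
  expect_equal(max(z$power), 0)
  # unit white noise: power in 4-24 Hz ~ 20/(fs/2) of total variance
  set.seed(7)
  x <- matrix(rnorm(500 * 200), 500, 200)
  ps <- multitaper_band_power(epochs_from_matrix(x, fs))
  frac <- mean(apply(ps$power, 1, sum)) / mean(apply(x, 2, var))
  expect_equal(frac, 20 / 125, tolerance = 0.1)
  # 9 Hz sinusoid: >= 90% of the 4-24 Hz power lands in alpha1,
  # in agreement with a plain periodogram oracle
  t <- seq_len(500) / fs
  s <- cbind(sin(2 * pi * 9 * t))
  pss <- multitaper_band_power(epochs_from_matrix(s, fs))
  expect_gt(pss$power[1, 1, "alpha1"] / sum(pss$power[1, 1, ]), 0.9)
  pg <- Mod(fft(s[, 1]))^2
  freqs <- (seq_len(500) - 1) * fs / 500
  in_band <- function(lo, hi) sum(pg[freqs >= lo & freqs < hi & freqs <= fs / 2])
  expect_gt(in_band(8, 10) / in_band(4, 24), 0.9)
  # too-short epochs are refused
  expect_error(multitaper_band_power(epochs_from_matrix(cbind(rnorm(100)), fs)),
               "too short")
})

test_that("relative power partitions to one per channel and flags zero epochs", {
  coh <- generate_cohort(small_cohort(seed = 2, n_subj = 2, n_ch = 6, n_ep = 4))
  psd <- multitaper_band_power(coh$epochs)
  rp <- relative_power(psd)
  n_ch <- 6
  for (ch in seq_len(n_ch)) {
    sums <- rowSums(rp[, (ch - 1) * 7 + 1:7, drop = FALSE])
    expect_equal(sums, rep(1, nrow(rp)), tolerance = 1e-12)
  }
  expect_equal(attr(rp, "pipeline"), "handcrafted")
  expect_true(all(grepl("^E\\d+_(theta|alpha|beta)\\d$", colnames(rp))))
  # all power in one band
  t <- seq_len(500) / 250
  pss <- multitaper_band_power(epochs_from_matrix(cbind(sin(2 * pi * 9 * t))))
  rp1 <- relative_power(pss)
  expect_gt(rp1[1, "E001_alpha1"], 0.9)
  # zero epoch -> uniform 1/K with a warning
  z <- multitaper_band_power(epochs_from_matrix(cbind(rep(0, 500))))
  expect_warning(rpz <- relative_power(z), "zero total power")
  expect_equal(unname(as.numeric(rpz[1, ])), rep(1 / 7, 7), tolerance = 1e-12)
})

test_that("white-noise relative power is close to bandwidth / 20", {
  set.seed(9)
  x <- matrix(rnorm(500 * 100), 500, 100)
  rp <- relative_power(multitaper_band_power(epochs_from_matrix(x)))
  bands <- default_bands()
  expected <- (bands$high - bands$low) / 20
  got <- colMeans(rp)[paste0("E001_", bands$name)]
  expect_equal(unname(got), expected, tolerance = 0.1)
})
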