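# Shared fixtures: all synthetic, built in code at test time.

# Random symmetric positive-definite matrix with well-spread spectrum.
random_spd <- function(n, seed = 1, scale = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  S <- crossprod(A) / n + diag(n) * 0.5
  S * scale
}

# A band_covariance_set whose per-band class means are exactly S1 (class "M")
# and S2 (class "H"): one epoch per class carrying the matrix itself.
covset_from_pair <- function(S1, S2, bands = default_bands()[1, ]) {
  N <- nrow(S1)
  cube <- array(0, dim = c(N, N, 2))
  cube[, , 1] <- S1
  cube[, , 2] <- S2
  covs <- rep(list(cube), nrow(bands))
  names(covs) <- bands$name
  structure(list(cov = covs, bands = bands,
                 ch_names = sprintf("E%03d", seq_len(N)), shrinkage = 0,
                 subject = c("S1", "S2"), group = c("M", "H"),
                 task = c("t", "t")),
            class = "band_covariance_set")
}

# Minimal band_epochs wrapper around an epochs x channels x samples array.
band_epochs_from_array <- function(x, bands = default_bands()[1, ], fs = 250) {
  d <- dim(x)
  arr <- array(0, dim = c(nrow(bands), d[1], d[2], d[3]))
  for (k in seq_len(nrow(bands))) arr[k, , , ] <- x
  structure(list(data = arr, bands = bands, fs = fs,
                 ch_names = sprintf("E%03d", seq_len(d[2])), positions = NULL,
                 subject = rep("S1", d[1]), group = rep("M", d[1]),
                 task = rep("t", d[1])),
            class = "band_epochs")
}

# Single-channel-per-epoch epoch_set from a samples x epochs matrix.
epochs_from_matrix <- function(x, fs = 250, n_channels = 1) {
  n_ep <- ncol(x)
  arr <- array(0, dim = c(n_ep, n_channels, nrow(x)))
  for (e in seq_len(n_ep)) for (ch in seq_len(n_channels)) arr[e, ch, ] <- x[, e]
  epoch_set(arr, fs, sprintf("E%03d", seq_len(n_channels)),
            subject = rep("S1", n_ep), group = rep("M", n_ep),
            task = rep("t", n_ep))
}

# Small planted-effect cohort used by several decoding tests.
small_cohort <- function(seed = 1, ratio = 2, n_subj = 6, n_ch = 12,
                         n_ep = 10, noise_sd = 0.5, subject_sd = 0.2,
                         topology = "dense", band = "alpha1") {
  eff <- list(); eff[[band]] <- ratio
  cohort_config(n_subjects_per_group = n_subj, n_channels = n_ch,
                n_epochs_per_subject_per_task = n_ep, tasks = "verb",
                band_effects = eff, noise_sd = noise_sd,
                subject_sd = subject_sd, source_topology = topology,
                seed = seed)
}

subject_groups <- function(es) {
  us <- unique(es$subject)
  list(subjects = us, groups = es$group[match(us, es$subject)])
}

# Complex frequency response of a digital filter at frequency f (Hz).
filter_gain <- function(bt, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(bt$b) - 1))
  num <- sum(bt$b * z)
  z <- exp(-1i * w * (seq_along(bt$a) - 1))
  den <- sum(bt$a * z)
  Mod(num / den)
}
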