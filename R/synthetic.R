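#' Configuration for a synthetic EEG cohort
#'
#' Describes a two-group cohort generated through a linear forward model
#' `x(t) = A s(t) + eps(t)`: band-limited stochastic sources `s` (Butterworth-
#' filtered Gaussian noise, one band per source) are mixed into sensors by a
#' shared mixing matrix `A` and corrupted by white sensor noise. Group
#' differences are planted as multiplicative ratios on the variance of
#' selected sources for group "M" relative to the group-"H" baseline, with
#' per-subject lognormal jitter emulating between-subject variability.
#'
#' @param n_subjects_per_group Subjects in each of groups "M" and "H".
#' @param n_channels Number of sensors.
#' @param n_epochs_per_subject_per_task Epochs generated per subject and task.
#' @param fs Sampling rate (Hz); must exceed twice the highest band edge.
#' @param epoch_len Epoch length in seconds.
#' @param n_sources Number of latent sources; source k oscillates in band
#'   `((k - 1) %% K) + 1` of `bands`.
#' @param band_effects Named list mapping a band name to either a single
#'   power ratio (applied to the first source assigned to that band) or a
#'   list `list(source =, ratio =)`. Ratio r means group-M source variance is
#'   r times the group-H baseline.
#' @param subject_sd SD (log scale) of the per-subject lognormal jitter on
#'   source variances.
#' @param noise_sd SD of additive white sensor noise, same units as the
#'   mixed signal (microvolt scale).
#' @param seed Integer seed; cohorts are bit-identical given the config.
#' @param tasks Task labels cycled over for each subject.
#' @param source_topology `"dense"` (Gaussian mixing columns, the default) or
#'   `"patch"` (each source loads only its `patch_size` spatially nearest
#'   channels - useful when ground-truth spatial extent must be known).
#' @param patch_size Channels per source patch when `source_topology="patch"`.
#' @param per_subject_mixing_sd SD of optional per-subject Gaussian
#'   perturbation of the mixing matrix (0 = shared topography).
#' @param bands Band table (see [default_bands()]).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_group = 10,
                          n_channels = 24,
                          n_epochs_per_subject_per_task = 40,
                          fs = 250,
                          epoch_len = 2,
                          n_sources = 7,
                          band_effects = list(),
                          subject_sd = 0.2,
                          noise_sd = 0.5,
                          seed = 1L,
                          tasks = c("verb", "ar", "sq"),
                          source_topology = c("dense", "patch"),
                          patch_size = 6,
                          per_subject_mixing_sd = 0,
                          bands = default_bands()) {
  source_topology <- match.arg(source_topology)
  bands <- validate_bands(bands, fs = fs)
  counts <- c(n_subjects_per_group, n_channels,
              n_epochs_per_subject_per_task, n_sources)
  if (any(counts < 1)) stop_invalid("all counts must be >= 1")
  if (fs <= 2 * max(bands$high))
    stop_invalid("fs must exceed twice the highest band edge")
  K <- nrow(bands)
  source_bands <- bands$name[((seq_len(n_sources) - 1) %% K) + 1]
  effects <- normalize_band_effects(band_effects, bands$name, source_bands)
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_channels = as.integer(n_channels),
    n_epochs_per_subject_per_task = as.integer(n_epochs_per_subject_per_task),
    fs = fs, epoch_len = epoch_len,
    n_sources = as.integer(n_sources),
    band_effects = effects,
    subject_sd = subject_sd, noise_sd = noise_sd,
    seed = as.integer(seed), tasks = tasks,
    source_topology = source_topology, patch_size = as.integer(patch_size),
    per_subject_mixing_sd = per_subject_mixing_sd,
    bands = bands, source_bands = source_bands
  ), class = "cohort_config")
}

# Internal: canonical band_effects representation as a data frame
# (band, source, ratio), validated against the band list and source count.
normalize_band_effects <- function(band_effects, band_names, source_bands) {
  if (length(band_effects) == 0)
    return(data.frame(band = character(0), source = integer(0),
                      ratio = numeric(0)))
  if (is.null(names(band_effects)) || any(names(band_effects) == ""))
    stop_invalid("`band_effects` must be a named list (band name -> effect)")
  rows <- lapply(names(band_effects), function(bn) {
    if (!bn %in% band_names)
      stop_invalid("band_effects references unknown band `", bn, "`")
    ef <- band_effects[[bn]]
    if (is.numeric(ef) && length(ef) == 1) {
      src <- which(source_bands == bn)[1]
      if (is.na(src))
        stop_invalid("no source is assigned to band `", bn, "`")
      ratio <- ef
    } else if (is.list(ef)) {
      src <- ef$source
      ratio <- ef$ratio
      if (is.null(src) || is.null(ratio))
        stop_invalid("band_effects entries must be a ratio or list(source, ratio)")
      if (src < 1 || src > length(source_bands))
        stop_invalid("band_effects references unknown source ", src)
      if (source_bands[src] != bn)
        stop_invalid("source ", src, " oscillates in band `",
                     source_bands[src], "`, not `", bn, "`")
    } else stop_invalid("invalid band_effects entry for band `", bn, "`")
    if (ratio <= 0) stop_invalid("power ratios must be > 0")
    data.frame(band = bn, source = as.integer(src), ratio = ratio)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic two-group EEG cohort
#'
#' Draws a cohort under the forward model described in [cohort_config()].
#' Every epoch is `A %*% s(t) + eps(t)` where each source trace is order-4
#' Butterworth band-pass filtered Gaussian noise, rescaled so its sample
#' variance equals the subject's source variance exactly. Group-M subjects
#' have the planted sources' variances multiplied by the configured ratio;
#' all subjects receive independent lognormal jitter (mean 1) on every
#' source variance.
#'
#' @param config A `cohort_config`.
#' @return A list of class `bandcov_cohort` with elements
#'   \describe{
#'     \item{epochs}{the generated `epoch_set`}
#'     \item{forward}{list with the mixing matrix `A` (channels x sources),
#'       `source_bands`, and the planted `effects` table}
#'     \item{source_variances}{subjects x sources matrix of realized source
#'       variances}
#'     \item{montage}{the sensor montage}
#'   }
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects_per_group = 2, n_channels = 8,
#'                      n_epochs_per_subject_per_task = 2, tasks = "verb",
#'                      band_effects = list(alpha1 = 2))
#' coh <- generate_cohort(cfg)
#' coh$epochs
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  N <- config$n_channels
  S <- config$n_sources
  K <- nrow(config$bands)
  fs <- config$fs
  nsamp <- round(config$epoch_len * fs)
  mont <- generate_montage(N, config$seed)

  A <- switch(config$source_topology,
    dense = {
      A0 <- matrix(rnorm(N * S), N, S)
      sweep(A0, 2, sqrt(colSums(A0^2)), "/")
    },
    patch = {
      A0 <- matrix(0, N, S)
      centers <- sample.int(N, S, replace = S > N)
      d <- as.matrix(stats::dist(mont$positions))
      for (k in seq_len(S)) {
        near <- order(d[centers[k], ])[seq_len(min(config$patch_size, N))]
        A0[near, k] <- 1
      }
      sweep(A0, 2, sqrt(colSums(A0^2)), "/")
    })
  rownames(A) <- mont$ch_names

  # per-band filter sections (order 4 Butterworth, zero-phase applied)
  filt <- lapply(seq_len(K), function(k) {
    butter_bandpass_sos(4, config$bands$low[k], config$bands$high[k], fs)
  })
  band_of_source <- match(config$source_bands, config$bands$name)

  n_subj <- 2 * config$n_subjects_per_group
  subjects <- sprintf("S%02d", seq_len(n_subj))
  groups <- rep(c("M", "H"), each = config$n_subjects_per_group)
  ratio_vec <- rep(1, S)
  if (nrow(config$band_effects) > 0)
    ratio_vec[config$band_effects$source] <- config$band_effects$ratio

  n_task <- length(config$tasks)
  n_ep_subj <- config$n_epochs_per_subject_per_task * n_task
  n_ep <- n_subj * n_ep_subj
  data <- array(0, dim = c(n_ep, N, nsamp))
  lab_subject <- character(n_ep)
  lab_group <- character(n_ep)
  lab_task <- character(n_ep)
  source_var <- matrix(0, n_subj, S,
                       dimnames = list(subjects, config$source_bands))

  e <- 0L
  for (si in seq_len(n_subj)) {
    v <- (if (groups[si] == "M") ratio_vec else rep(1, S)) *
      rlnorm(S, meanlog = -config$subject_sd^2 / 2, sdlog = config$subject_sd)
    source_var[si, ] <- v
    As <- A
    if (config$per_subject_mixing_sd > 0) {
      As <- A + matrix(rnorm(N * S, sd = config$per_subject_mixing_sd), N, S)
      As <- sweep(As, 2, sqrt(colSums(As^2)), "/")
    }
    for (ti in seq_len(n_task)) {
      for (ei in seq_len(config$n_epochs_per_subject_per_task)) {
        z <- matrix(rnorm(nsamp * S), nsamp, S)
        for (k in unique(band_of_source)) {
          cols <- which(band_of_source == k)
          z[, cols] <- .filtfilt_sos(filt[[k]], z[, cols, drop = FALSE])
        }
        z <- sweep(z, 2, colMeans(z))
        z <- sweep(z, 2, sqrt(v / apply(z, 2, var)), "*")
        x <- As %*% t(z)
        if (config$noise_sd > 0)
          x <- x + matrix(rnorm(N * nsamp, sd = config$noise_sd), N, nsamp)
        e <- e + 1L
        data[e, , ] <- x
        lab_subject[e] <- subjects[si]
        lab_group[e] <- groups[si]
        lab_task[e] <- config$tasks[ti]
      }
    }
  }

  es <- epoch_set(data, fs, mont$ch_names, mont$positions,
                  subject = lab_subject, group = lab_group, task = lab_task)
  structure(list(
    epochs = es,
    forward = list(A = A, source_bands = config$source_bands,
                   effects = config$band_effects),
    source_variances = source_var,
    montage = mont,
    config = config
  ), class = "bandcov_cohort")
}

#' Generate a null cohort (no group effect)
#'
#' Identical to [generate_cohort()] with every planted power ratio forced to
#' 1, so the group labels are exchangeable by construction. Used as the
#' type-I-error harness for the cluster permutation test and as the chance
#' baseline for classifiers.
#'
#' @param config A `cohort_config`.
#' @return An `epoch_set`.
#' @export
null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(config$band_effects) > 0) config$band_effects$ratio[] <- 1
  generate_cohort(config)$epochs
}

#' @export
print.bandcov_cohort <- function(x, ...) {
  cat("<bandcov_cohort>\n")
  print(x$epochs)
  if (nrow(x$forward$effects) > 0) {
    cat("  planted effects:\n")
    for (i in seq_len(nrow(x$forward$effects)))
      cat(sprintf("    %s (source %d): M/H power ratio %.2f\n",
                  x$forward$effects$band[i], x$forward$effects$source[i],
                  x$forward$effects$ratio[i]))
  } else cat("  no planted effects (null cohort)\n")
  invisible(x)
}
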