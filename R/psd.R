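# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem (Slepian tapers). Cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  W <- nw / n
  t <- seq_len(n) - 1
  M <- matrix(0, n, n)
  diag(M) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off <- t[-1] * (n - t[-1]) / 2
  M[cbind(2:n, 1:(n - 1))] <- off
  M[cbind(1:(n - 1), 2:n)] <- off
  eg <- eigen(M, symmetric = TRUE)
  H <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    h <- H[, j]
    h <- h / sqrt(sum(h^2))
    if (h[which.max(abs(h))] < 0) h <- -h
    H[, j] <- h
  }
  .dpss_cache[[key]] <- H
  H
}

#' Multitaper band power per epoch and channel
#'
#' Power spectral density estimated by averaging periodograms over `n_tapers`
#' orthogonal Slepian tapers (time-bandwidth product `nw`), then integrated
#' over each band's frequency range. With the default `nw = 2` on 2-s epochs
#' the spectral half-bandwidth is 1 Hz, which resolves the narrowest (2 Hz)
#' analysis bands.
#'
#' @param epochs An `epoch_set`.
#' @param bands Band table.
#' @param nw Time-bandwidth product (half-bandwidth = `nw / epoch_len` Hz).
#' @param n_tapers Number of tapers (at most `2 * nw - 1`).
#' @return An object of class `psd_set`: list with `power` (epochs x channels
#'   x bands array of integrated band power, signal-units squared),
#'   `total_power` (epochs x channels, integral over the full one-sided
#'   spectrum), `bands` and the epoch labels.
#' @export
multitaper_band_power <- function(epochs, bands = default_bands(),
                                  nw = 2, n_tapers = 3) {
  stopifnot(inherits(epochs, "epoch_set"))
  bands <- validate_bands(bands, fs = epochs$fs)
  d <- dim(epochs$data)
  n_ep <- d[1]; N <- d[2]; n <- d[3]
  fs <- epochs$fs
  min_bw <- min(bands$high - bands$low)
  if (n / fs < 2 / min_bw)
    stop_invalid("epoch too short (", n / fs, " s) to resolve a ", min_bw,
                 " Hz band; need at least ", 2 / min_bw, " s")
  if (n_tapers > 2 * nw - 1)
    stop_invalid("n_tapers must be at most 2*nw - 1")
  H <- dpss_tapers(n, nw, n_tapers)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- which(freqs <= fs / 2)
  df <- fs / n
  K <- nrow(bands)
  bins <- lapply(seq_len(K),
                 function(k) which(freqs[half] >= bands$low[k] &
                                   freqs[half] < bands$high[k]))
  power <- array(0, dim = c(n_ep, N, K),
                 dimnames = list(NULL, epochs$ch_names, bands$name))
  total <- matrix(0, n_ep, N, dimnames = list(NULL, epochs$ch_names))
  for (e in seq_len(n_ep)) {
    x <- t(epochs$data[e, , , drop = TRUE])      # samples x channels
    if (N == 1) x <- matrix(epochs$data[e, 1, ], ncol = 1)
    psd <- matrix(0, length(half), N)
    for (j in seq_len(n_tapers)) {
      Fx <- mvfft(x * H[, j])
      psd <- psd + (Mod(Fx[half, , drop = FALSE])^2) * (2 / fs)
    }
    psd <- psd / n_tapers
    for (k in seq_len(K))
      power[e, , k] <- colSums(psd[bins[[k]], , drop = FALSE]) * df
    total[e, ] <- colSums(psd) * df
  }
  structure(list(power = power, total_power = total, bands = bands, fs = fs,
                 ch_names = epochs$ch_names, positions = epochs$positions,
                 subject = epochs$subject, group = epochs$group,
                 task = epochs$task, nw = nw, n_tapers = n_tapers),
            class = "psd_set")
}

#' @export
print.psd_set <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<psd_set> %d epochs x %d channels x %d bands (multitaper nw=%g, %d tapers)\n",
              d[1], d[2], d[3], x$nw, x$n_tapers))
  invisible(x)
}

#' Relative band power features
#'
#' Divides each band power by a per-(epoch, channel) total so the seven
#' values of a channel sum to one. By default the denominator is the summed
#' power over the analysis bands themselves (their union, 4-24 Hz), which
#' makes the normalization an exact partition; `denominator = "full_spectrum"`
#' instead divides by the integral over the whole one-sided spectrum.
#'
#' Epochs with zero total power in some channel are assigned the uniform
#' value 1/K there, flagged, and reported with a warning.
#'
#' @param psd A `psd_set`.
#' @param denominator `"band_union"` (default) or `"full_spectrum"`.
#' @return A `feature_matrix` (epochs x channels*bands) with feature names
#'   `"<channel>_<band>"` and pipeline tag `"handcrafted"`. Flagged epochs
#'   are recorded in `attr(x, "flagged")`.
#' @export
relative_power <- function(psd, denominator = c("band_union", "full_spectrum")) {
  stopifnot(inherits(psd, "psd_set"))
  denominator <- match.arg(denominator)
  d <- dim(psd$power)
  n_ep <- d[1]; N <- d[2]; K <- d[3]
  denom <- switch(denominator,
                  band_union = apply(psd$power, c(1, 2), sum),
                  full_spectrum = psd$total_power)
  zero <- denom <= 0
  flagged <- which(apply(zero, 1, any))
  if (length(flagged) > 0)
    warning("zero total power in ", length(flagged),
            " epoch(s); assigned uniform relative power 1/K")
  rel <- array(0, dim = d)
  for (k in seq_len(K)) {
    p <- matrix(psd$power[, , k], n_ep, N)
    r <- p / ifelse(zero, 1, denom)
    r[zero] <- 1 / K
    rel[, , k] <- r
  }
  # layout: channel-major blocks, bands within channel
  vals <- matrix(0, n_ep, N * K)
  nm <- character(N * K)
  for (ch in seq_len(N)) {
    idx <- (ch - 1) * K + seq_len(K)
    vals[, idx] <- matrix(rel[, ch, ], n_ep, K)
    nm[idx] <- paste0(psd$ch_names[ch], "_", psd$bands$name)
  }
  fm <- feature_matrix(vals, nm, pipeline = "handcrafted")
  attr(fm, "flagged") <- flagged
  fm
}

#' Construct a feature matrix
#'
#' Epochs x features container shared by the three pipelines.
#'
#' @param values Numeric matrix (epochs x features), all finite.
#' @param feature_names Unique feature names.
#' @param pipeline Provenance tag (e.g. `"supervised"`, `"riemannian"`,
#'   `"handcrafted"`).
#' @return An object of class `feature_matrix` (a numeric matrix with
#'   attributes).
#' @export
feature_matrix <- function(values, feature_names, pipeline = "custom") {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop_invalid("feature values must be finite")
  if (length(feature_names) != ncol(values))
    stop_invalid("feature_names length must equal ncol(values)")
  if (anyDuplicated(feature_names))
    stop_invalid("feature names must be unique")
  colnames(values) <- feature_names
  structure(values, pipeline = pipeline,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (pipeline: %s)\n",
              nrow(x), ncol(x), attr(x, "pipeline")))
  invisible(x)
}
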