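#' Convert backward-model filters to forward-model activation patterns
#'
#' A spatial filter `w` (a backward model) tells how to *extract* a latent
#' signal from the sensors; the corresponding activation pattern
#' `A = Sigma_X W` (the forward model, equal to `Cov[x_i, s_hat_i]` up to the
#' extracted-signal covariance) tells how that signal *projects onto* the
#' sensors and is the interpretable topography. The extracted-signal
#' covariance scaling is taken as identity by default (patterns are
#' scale-free and column-normalized to unit maximum absolute value); pass
#' `sigma_s` to apply the full `Sigma_s^{-1}` scaling.
#'
#' @param W Either a numeric filter matrix (features/channels x J) or a
#'   `spatial_filters` object (then `sigma_x` must be a
#'   `band_covariance_set`, typically over the training epochs, and patterns
#'   are computed per band against the band-mean covariance).
#' @param sigma_x Feature/channel covariance matrix (symmetric PSD), or the
#'   `band_covariance_set` when `W` is a `spatial_filters`.
#' @param sigma_s Optional covariance of the extracted signals, applied as
#'   `A = Sigma_X W Sigma_s^{-1}`.
#' @param normalize Column-normalize each pattern to unit max |value|
#'   (default TRUE).
#' @return For matrix input: the pattern matrix (same shape as `W`). For
#'   `spatial_filters`: an object of class `pattern_map` (per-band `N x J`
#'   pattern matrices).
#' @export
filters_to_patterns <- function(W, sigma_x, sigma_s = NULL, normalize = TRUE) {
  if (inherits(W, "spatial_filters")) {
    if (!inherits(sigma_x, "band_covariance_set"))
      stop_invalid("with spatial filters, `sigma_x` must be a band_covariance_set")
    pats <- lapply(seq_along(W$filters), function(k) {
      Sbar <- apply(sigma_x$cov[[k]], c(1, 2), mean)
      pattern_of(W$filters[[k]]$W, Sbar, sigma_s, normalize)
    })
    names(pats) <- sigma_x$bands$name
    return(structure(list(patterns = pats, bands = sigma_x$bands,
                          ch_names = sigma_x$ch_names, mode = W$mode),
                     class = "pattern_map"))
  }
  W <- as.matrix(W)
  sigma_x <- as.matrix(sigma_x)
  if (nrow(sigma_x) != ncol(sigma_x) || nrow(sigma_x) != nrow(W))
    stop_invalid("shape mismatch between `W` and `sigma_x`")
  if (max(abs(sigma_x - t(sigma_x))) > 1e-8 * max(1, max(abs(sigma_x))))
    stop_invalid("`sigma_x` must be symmetric")
  pattern_of(W, sigma_x, sigma_s, normalize)
}

pattern_of <- function(W, sigma_x, sigma_s, normalize) {
  A <- sigma_x %*% W
  if (!is.null(sigma_s)) A <- A %*% solve(sigma_s)
  if (normalize) {
    mx <- apply(abs(A), 2, max)
    mx[mx == 0] <- 1
    A <- sweep(A, 2, mx, "/")
  }
  rownames(A) <- rownames(sigma_x) %||% rownames(W)
  A
}

#' @export
print.pattern_map <- function(x, ...) {
  cat(sprintf("<pattern_map> %s: %d bands x (%d channels x %d components)\n",
              x$mode, length(x$patterns), nrow(x$patterns[[1]]),
              ncol(x$patterns[[1]])))
  invisible(x)
}

#' Numerical rank report for a stacked filter matrix
#'
#' Reports the numerical column rank (singular values above
#' `tol * max(singular value)`) of a stacked multi-band filter matrix and
#' whether it has full column rank - the condition under which the joint
#' backward model is invertible enough for pattern interpretation.
#'
#' @param W Numeric matrix (e.g. `NK x J` stacked filters).
#' @param tol Relative singular-value tolerance (default 1e-10).
#' @return A list with `rank`, `full_column_rank` and `singular_values`.
#' @export
rank_check <- function(W, tol = 1e-10) {
  W <- as.matrix(W)
  sv <- svd(W, nu = 0, nv = 0)$d
  rk <- sum(sv > tol * sv[1])
  list(rank = rk, full_column_rank = rk == ncol(W), singular_values = sv)
}
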