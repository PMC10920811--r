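#' Fit supervised spatial filters (CSP) per band
#'
#' For each band, solves the generalized eigenproblem
#' `Sigma_1 w = lambda (Sigma_1 + Sigma_2) w`, where `Sigma_c` is the
#' arithmetic mean covariance of class `c` over the training epochs. Filters
#' are the eigenvectors of the `J` largest eigenvalues ("sorted by decreasing
#' eigenvalues"; they maximize the filtered-signal variance of class 1
#' relative to the total), normalized so that
#' `w' (Sigma_1 + Sigma_2) w = 1`. The log-variances of the class-1 mean
#' covariance after projection are stored as the reference for
#' [csp_log_features()].
#'
#' @param covset A `band_covariance_set` (training epochs only).
#' @param labels Class label per epoch (2 classes); defaults to the group
#'   labels stored in `covset`.
#' @param J Number of filters per band (`J <= N`).
#' @param class1 The "first class" whose variance is maximized and whose mean
#'   covariance anchors the log features (default `"M"`).
#' @param select `"top"` (default; decreasing-eigenvalue order) or `"both"`
#'   (alternate ends of the spectrum, common CSP practice).
#' @return An object of class `spatial_filters` with per-band filter matrices
#'   `W` (`N x J`), eigenvalues, and the class-1 reference log-variances.
#' @export
csp_fit <- function(covset, labels = covset$group, J, class1 = "M",
                    select = c("top", "both")) {
  stopifnot(inherits(covset, "band_covariance_set"))
  select <- match.arg(select)
  N <- length(covset$ch_names)
  if (J > N) stop_invalid("J must be at most the number of channels (", N, ")")
  cls <- unique(labels)
  if (length(cls) != 2)
    stop("CSP requires exactly two classes, got ", length(cls), call. = FALSE)
  if (!class1 %in% cls) class1 <- sort(cls)[1]
  class2 <- setdiff(cls, class1)

  per_band <- lapply(covset$cov, function(cube) {
    S1 <- apply(cube[, , labels == class1, drop = FALSE], c(1, 2), mean)
    S2 <- apply(cube[, , labels == class2, drop = FALSE], c(1, 2), mean)
    C <- S1 + S2
    is <- spd_invsqrt(C)
    M <- is %*% S1 %*% is
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    ord <- switch(select,
                  top = seq_len(J),
                  both = {
                    n <- length(eg$values)
                    idx <- integer(0)
                    lo <- 1; hi <- n
                    for (j in seq_len(J)) {
                      if (j %% 2 == 1) { idx <- c(idx, lo); lo <- lo + 1 }
                      else { idx <- c(idx, hi); hi <- hi - 1 }
                    }
                    idx
                  })
    W <- is %*% eg$vectors[, ord, drop = FALSE]
    lambda <- eg$values[ord]
    ref_logvar <- log(pmax(diag(t(W) %*% S1 %*% W), 1e-300))
    list(W = W, eigenvalues = lambda, ref_logvar = ref_logvar,
         S1 = S1, S2 = S2)
  })
  structure(list(filters = per_band, bands = covset$bands,
                 ch_names = covset$ch_names, J = as.integer(J),
                 mode = "supervised-CSP", class1 = class1, class2 = class2,
                 select = select),
            class = "spatial_filters")
}

#' CSP log-variance features
#'
#' For each band and epoch, projects the epoch covariance through the fitted
#' filters (`Z_i = W' Sigma_i W`) and takes
#' `log(diag(Z_i)) - log(diag(W' Sigma_1 W))`: the log filtered-signal
#' variance relative to the class-1 training mean. Features of all bands are
#' concatenated, giving `K * J` columns.
#'
#' @param covset A `band_covariance_set`.
#' @param filters Supervised `spatial_filters` from [csp_fit()].
#' @return A `feature_matrix` (pipeline `"supervised"`), feature names
#'   `"<band>_csp<j>"`.
#' @export
csp_log_features <- function(covset, filters) {
  stopifnot(inherits(covset, "band_covariance_set"),
            inherits(filters, "spatial_filters"))
  if (filters$mode != "supervised-CSP")
    stop_invalid("filters were not fitted in supervised mode")
  K <- length(covset$cov)
  J <- filters$J
  n_ep <- dim(covset$cov[[1]])[3]
  vals <- matrix(0, n_ep, K * J)
  nm <- character(K * J)
  floored <- FALSE
  for (k in seq_len(K)) {
    fb <- filters$filters[[k]]
    Z <- .project_cov_cube(covset$cov[[k]], fb$W)
    dvar <- t(apply(Z, 3, diag))
    if (J == 1) dvar <- matrix(apply(Z, 3, diag), ncol = 1)
    if (any(dvar <= 0)) {
      floored <- TRUE
      dvar[dvar <= 0] <- 1e-12
    }
    vals[, (k - 1) * J + seq_len(J)] <-
      sweep(log(dvar), 2, fb$ref_logvar)
    nm[(k - 1) * J + seq_len(J)] <-
      paste0(covset$bands$name[k], "_csp", seq_len(J))
  }
  if (floored)
    warning("non-positive projected variances floored at 1e-12")
  feature_matrix(vals, nm, pipeline = "supervised")
}

#' Fit unsupervised spatial filters (PCA) per band
#'
#' Per band, the filters are the top-`J` eigenvectors (decreasing
#' eigenvalues) of the arithmetic mean covariance across all training epochs,
#' classes pooled - a projection to a common low-dimensional space shared by
#' both groups.
#'
#' @param covset A `band_covariance_set` (training epochs only).
#' @param J Number of components per band (`J <= N`).
#' @param pca_on `"mean_cov"` (default): eigenvectors of the grand-mean
#'   covariance; `"pooled"`: eigenvectors of the average second-moment over
#'   pooled epochs (identical here since epoch covariances are already
#'   centered per epoch, retained as an explicit option).
#' @return An object of class `spatial_filters` (mode `"unsupervised-PCA"`).
#' @export
pca_fit <- function(covset, J, pca_on = c("mean_cov", "pooled")) {
  stopifnot(inherits(covset, "band_covariance_set"))
  pca_on <- match.arg(pca_on)
  N <- length(covset$ch_names)
  if (J > N) stop_invalid("J must be at most the number of channels (", N, ")")
  per_band <- lapply(covset$cov, function(cube) {
    Sbar <- apply(cube, c(1, 2), mean)
    eg <- eigen((Sbar + t(Sbar)) / 2, symmetric = TRUE)
    list(W = eg$vectors[, seq_len(J), drop = FALSE],
         eigenvalues = eg$values[seq_len(J)],
         mean_cov = Sbar)
  })
  structure(list(filters = per_band, bands = covset$bands,
                 ch_names = covset$ch_names, J = as.integer(J),
                 mode = "unsupervised-PCA", pca_on = pca_on),
            class = "spatial_filters")
}

#' @export
print.spatial_filters <- function(x, ...) {
  cat(sprintf("<spatial_filters> %s, J = %d, %d bands x %d channels\n",
              x$mode, x$J, length(x$filters), length(x$ch_names)))
  invisible(x)
}

#' Project a covariance set through spatial filters
#'
#' Computes `W' Sigma_i W` per band and epoch (the covariance of the
#' spatially filtered signal).
#'
#' @param covset A `band_covariance_set`.
#' @param filters A `spatial_filters` object.
#' @return A list (one per band) of `J x J x epochs` arrays.
#' @export
project_covariances <- function(covset, filters) {
  stopifnot(inherits(covset, "band_covariance_set"),
            inherits(filters, "spatial_filters"))
  out <- lapply(seq_along(covset$cov), function(k)
    .project_cov_cube(covset$cov[[k]], filters$filters[[k]]$W))
  names(out) <- names(covset$cov)
  out
}

#' Riemannian tangent-space features for the unsupervised pipeline
#'
#' Per band: project covariances through the PCA filters, whiten by the
#' Karcher mean of the *training* projected covariances, vectorize the matrix
#' log, concatenate bands. The references must be fitted on training epochs
#' only and passed in.
#'
#' @param covset A `band_covariance_set` (epochs to featurize).
#' @param filters Unsupervised `spatial_filters` from [pca_fit()].
#' @param refs List of per-band `riemann_reference` objects (one per band).
#' @return A `feature_matrix` (pipeline `"riemannian"`), `K * J(J+1)/2`
#'   columns named `"<band>_ts_<r>.<c>"`.
#' @export
riemann_features <- function(covset, filters, refs) {
  stopifnot(inherits(covset, "band_covariance_set"))
  proj <- project_covariances(covset, filters)
  K <- length(proj)
  parts <- vector("list", K)
  for (k in seq_len(K)) {
    v <- tangent_vectorize(proj[[k]], refs[[k]])
    colnames(v) <- paste0(covset$bands$name[k], "_", colnames(v))
    parts[[k]] <- v
  }
  feature_matrix(do.call(cbind, parts),
                 unlist(lapply(parts, colnames)),
                 pipeline = "riemannian")
}

#' Fit the per-band Karcher-mean references for tangent features
#'
#' @param covset Training `band_covariance_set`.
#' @param filters Unsupervised `spatial_filters`.
#' @param tol,max_iter Passed to [riemannian_mean()].
#' @return List of `riemann_reference`, one per band.
#' @export
riemann_fit_references <- function(covset, filters, tol = 1e-8, max_iter = 50) {
  proj <- project_covariances(covset, filters)
  lapply(proj, riemannian_mean, tol = tol, max_iter = max_iter)
}
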