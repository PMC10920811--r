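# Symmetric-eigendecomposition matrix functions with an eigenvalue floor.
# The floor (default 1e-12) guards log/invsqrt against numerically zero
# eigenvalues; genuinely non-PD input is reported by spd_check().

sym_fun <- function(S, f, eigfloor = 1e-12) {
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, eigfloor)
  eg$vectors %*% (f(ev) * t(eg$vectors))
}

spd_sqrt <- function(S, eigfloor = 1e-12) sym_fun(S, sqrt, eigfloor)
spd_invsqrt <- function(S, eigfloor = 1e-12) sym_fun(S, function(v) 1 / sqrt(v), eigfloor)
spd_logm <- function(S, eigfloor = 1e-12) sym_fun(S, log, eigfloor)
spd_expm <- function(S) sym_fun(S, exp, eigfloor = -Inf)

# Internal: error unless S is symmetric (to tol) positive definite.
spd_check <- function(S, tol = 1e-10, what = "matrix") {
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S))))
    stop_invalid(what, " is not symmetric")
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_invalid(what, " is not positive definite (min eigenvalue ",
                 format(min(ev)), ")")
  invisible(TRUE)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `delta(A, B) = ||log(A^{-1/2} B A^{-1/2})||_F`, equivalently the root sum
#' of squared log-eigenvalues of `A^{-1} B`. Invariant under congruence
#' transforms `X -> G X G'`.
#'
#' @param A,B Symmetric positive-definite matrices of equal dimension.
#' @return The distance (non-negative scalar).
#' @export
airm_distance <- function(A, B) {
  spd_check(A, what = "A"); spd_check(B, what = "B")
  is <- spd_invsqrt(A)
  M <- is %*% B %*% is
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

# Coerce a list of matrices / 3-D array to an N x N x m array.
as_spd_cube <- function(mats) {
  if (is.list(mats)) {
    N <- nrow(mats[[1]])
    cube <- array(0, dim = c(N, N, length(mats)))
    for (i in seq_along(mats)) cube[, , i] <- mats[[i]]
    cube
  } else if (is.array(mats) && length(dim(mats)) == 3) {
    mats
  } else if (is.matrix(mats)) {
    array(mats, dim = c(nrow(mats), ncol(mats), 1))
  } else stop_invalid("expected a list of matrices or a 3-D array")
}

#' Karcher (Fréchet) mean of SPD matrices under the affine-invariant metric
#'
#' Fixed-point iteration: starting from the arithmetic mean, repeatedly move
#' along the mean of the logarithms of the whitened matrices until the
#' gradient `mean(log(M^{-1/2} S_i M^{-1/2}))` has Frobenius norm below
#' `tol`. This is the reference point for tangent-space vectorization.
#'
#' @param mats List of SPD matrices or an `N x N x m` array.
#' @param tol Convergence tolerance on the gradient norm (default 1e-8).
#' @param max_iter Maximum iterations (default 50); non-convergence is an
#'   error reporting the final gradient norm.
#' @return An object of class `riemann_reference`: list with `mean`,
#'   `invsqrt` (its inverse square root), `iterations` and `gradient_norm`.
#' @export
#' @examples
#' S1 <- diag(c(1, 4)); S2 <- diag(c(4, 1))
#' riemannian_mean(list(S1, S2))$mean   # geodesic midpoint = 2 I
riemannian_mean <- function(mats, tol = 1e-8, max_iter = 50) {
  cube <- as_spd_cube(mats)
  for (i in seq_len(dim(cube)[3]))
    spd_check(cube[, , i], what = paste0("matrix ", i))
  M <- apply(cube, c(1, 2), mean)
  gn <- Inf
  for (it in seq_len(max_iter)) {
    is <- spd_invsqrt(M)
    G <- .mean_whitened_log(cube, is, 1e-12)
    gn <- sqrt(sum(G^2))
    if (gn <= tol) {
      ref <- structure(list(mean = M, invsqrt = is, iterations = it,
                            gradient_norm = gn),
                       class = "riemann_reference")
      return(ref)
    }
    sq <- spd_sqrt(M)
    M <- sq %*% spd_expm(G) %*% sq
    M <- (M + t(M)) / 2
  }
  stop("Karcher mean did not converge in ", max_iter,
       " iterations (gradient norm ", format(gn), ")", call. = FALSE)
}

#' @export
print.riemann_reference <- function(x, ...) {
  cat(sprintf("<riemann_reference> %dx%d mean SPD matrix (%d iterations, grad %.2e)\n",
              nrow(x$mean), ncol(x$mean), x$iterations, x$gradient_norm))
  invisible(x)
}

#' Tangent-space vectorization of SPD matrices
#'
#' Maps each SPD matrix `S_i` to the upper triangle (diagonal included) of
#' `log(R^{-1/2} S_i R^{-1/2})` where `R` is the reference (Karcher mean).
#' Off-diagonal entries are scaled by `offdiag_weight` (default `sqrt(2)`,
#' the isometry convention under which the Euclidean norm of the vector
#' equals the affine-invariant distance to the reference).
#'
#' @param covs List of SPD `J x J` matrices or a `J x J x m` array.
#' @param ref A `riemann_reference` (or an SPD matrix used as the reference).
#' @param offdiag_weight Weight applied to off-diagonal entries.
#' @return A numeric matrix, `m` x `J(J+1)/2`; columns are ordered
#'   column-major over the upper triangle and named `ts_<row>.<col>`.
#' @export
tangent_vectorize <- function(covs, ref, offdiag_weight = sqrt(2)) {
  cube <- as_spd_cube(covs)
  if (inherits(ref, "riemann_reference")) {
    is <- ref$invsqrt
  } else {
    spd_check(ref, what = "ref")
    is <- spd_invsqrt(ref)
  }
  if (nrow(is) != dim(cube)[1])
    stop_invalid("reference dimension does not match the matrices")
  out <- .tangent_batch(cube, is, offdiag_weight, 1e-12)
  J <- nrow(is)
  nm <- character(0)
  for (cc in seq_len(J)) nm <- c(nm, paste0("ts_", seq_len(cc), ".", cc))
  colnames(out) <- nm
  out
}
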