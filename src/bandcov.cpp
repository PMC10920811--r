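#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cascade of biquad sections (each row of `sos`: b0 b1 b2 a1 a2, a0 = 1),
// direct form II transposed, in place on a vector.
static void sos_filter(const arma::mat& sos, vec& x) {
  const int ns = sos.n_rows, n = x.n_elem;
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 3), a2 = sos(s, 4);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi + z2 - a1 * yi;
      z2 = b2 * xi - a2 * yi;
      x[i] = yi;
    }
  }
}

// Zero-phase filtering through second-order sections: numerically robust
// for narrow low-frequency bands where high-order direct forms lose
// precision. Columns filtered independently; odd end-reflection padding.
// [[Rcpp::export(name = ".filtfilt_sos")]]
arma::mat filtfilt_sos(const arma::mat& sos, const arma::mat& x) {
  const int n = x.n_rows, nc = x.n_cols;
  const int pad = 3 * (2 * (int)sos.n_rows + 1);
  if (n <= pad + 1)
    Rcpp::stop("series too short (%d samples) for filter padding (%d)", n, pad);
  mat out(n, nc);
  vec ext(n + 2 * pad);
  for (int c = 0; c < nc; ++c) {
    const vec xc = x.col(c);
    for (int i = 0; i < pad; ++i) ext[i] = 2.0 * xc[0] - xc[pad - i];
    ext.subvec(pad, pad + n - 1) = xc;
    for (int i = 0; i < pad; ++i)
      ext[pad + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];
    sos_filter(sos, ext);
    ext = reverse(ext);
    sos_filter(sos, ext);
    ext = reverse(ext);
    out.col(c) = ext.subvec(pad, pad + n - 1);
  }
  return out;
}

// Symmetric matrix log via eigendecomposition with an eigenvalue floor.
// Throws if an eigenvalue is non-positive beyond floor tolerance when
// strict checking is requested.
static mat sym_log(const mat& S, const double eigfloor, const bool strict) {
  vec ev;
  mat V;
  if (!eig_sym(ev, V, symmatu(S)))
    Rcpp::stop("symmetric eigendecomposition failed");
  if (strict && ev.min() <= 0.0)
    Rcpp::stop("matrix is not positive definite (min eigenvalue %g)", ev.min());
  ev = clamp(ev, eigfloor, datum::inf);
  return V * diagmat(log(ev)) * V.t();
}

// Mean of log(invsqrt %*% C_i %*% invsqrt) over slices: the Karcher-mean
// gradient at the point whose inverse square root is `invsqrt`.
// [[Rcpp::export(name = ".mean_whitened_log")]]
arma::mat mean_whitened_log(const arma::cube& C, const arma::mat& invsqrt,
                            const double eigfloor) {
  mat acc(invsqrt.n_rows, invsqrt.n_cols, fill::zeros);
  for (uword i = 0; i < C.n_slices; ++i)
    acc += sym_log(invsqrt * C.slice(i) * invsqrt, eigfloor, false);
  return acc / static_cast<double>(C.n_slices);
}

// Tangent-space vectorization: row i is the upper triangle (column-major,
// diagonal included) of log(invsqrt %*% C_i %*% invsqrt), off-diagonal
// entries scaled by `offdiag_weight`.
// [[Rcpp::export(name = ".tangent_batch")]]
arma::mat tangent_batch(const arma::cube& C, const arma::mat& invsqrt,
                        const double offdiag_weight, const double eigfloor) {
  const int J = invsqrt.n_rows;
  const int m = J * (J + 1) / 2;
  mat out(C.n_slices, m);
  for (uword i = 0; i < C.n_slices; ++i) {
    const mat L = sym_log(invsqrt * C.slice(i) * invsqrt, eigfloor, true);
    int k = 0;
    for (int c = 0; c < J; ++c)
      for (int r = 0; r <= c; ++r)
        out(i, k++) = (r == c) ? L(r, c) : offdiag_weight * L(r, c);
  }
  return out;
}

// W' C_i W for every slice.
// [[Rcpp::export(name = ".project_cov_cube")]]
arma::cube project_cov_cube(const arma::cube& C, const arma::mat& W) {
  cube out(W.n_cols, W.n_cols, C.n_slices);
  for (uword i = 0; i < C.n_slices; ++i)
    out.slice(i) = W.t() * C.slice(i) * W;
  return out;
}

// Largest |sum of T| over adjacency-connected supra-threshold clusters,
// per band (column of T), positive and negative excursions separately.
// nbr: per-channel integer vectors of 1-based neighbor indices.
// [[Rcpp::export(name = ".max_cluster_mass")]]
double max_cluster_mass(const arma::mat& T, const Rcpp::List& nbr,
                        const double thr) {
  const int N = T.n_rows, K = T.n_cols;
  double best = 0.0;
  std::vector<int> stack;
  std::vector<char> used(N);
  for (int k = 0; k < K; ++k) {
    for (int sgn = 0; sgn < 2; ++sgn) {
      std::fill(used.begin(), used.end(), 0);
      for (int c0 = 0; c0 < N; ++c0) {
        const double v = T(c0, k);
        const bool sup = sgn == 0 ? (v > thr) : (v < -thr);
        if (!sup || used[c0]) continue;
        double mass = 0.0;
        stack.clear();
        stack.push_back(c0);
        used[c0] = 1;
        while (!stack.empty()) {
          const int c = stack.back();
          stack.pop_back();
          mass += T(c, k);
          Rcpp::IntegerVector nb = nbr[c];
          for (int j = 0; j < nb.size(); ++j) {
            const int w = nb[j] - 1;
            const double tv = T(w, k);
            const bool s2 = sgn == 0 ? (tv > thr) : (tv < -thr);
            if (s2 && !used[w]) {
              used[w] = 1;
              stack.push_back(w);
            }
          }
        }
        if (std::abs(mass) > best) best = std::abs(mass);
      }
    }
  }
  return best;
}
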