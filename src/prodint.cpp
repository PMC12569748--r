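// Product-integral kernels for multistate estimation.
//
// All functions take the increments dA of a cumulative transition rate
// matrix as a K x K x m cube (m event times, rows summing to zero) and
// evaluate the product integral P(0, t_k) = prod_{j<=k} (I + dA_j) or
// functionals of it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Full prefix products P(0, t_k), k = 1..m.
// [[Rcpp::export]]
arma::cube prodint_prefix_cpp(const arma::cube& dA) {
  const arma::uword K = dA.n_rows, m = dA.n_slices;
  arma::cube out(K, K, m);
  arma::mat P(K, K, arma::fill::eye);
  arma::mat I(K, K, arma::fill::eye);
  for (arma::uword k = 0; k < m; ++k) {
    P = P * (I + dA.slice(k));
    out.slice(k) = P;
  }
  return out;
}

// Row `row` of the prefix products only: an m x K matrix with
// out(k, .) = e_row' * P(0, t_k).  O(m K^2), no cube allocation.
// [[Rcpp::export]]
arma::mat prodint_row_cpp(const arma::cube& dA, const int row) {
  const arma::uword K = dA.n_rows, m = dA.n_slices;
  arma::mat out(m, K);
  arma::rowvec p(K, arma::fill::zeros);
  p(row) = 1.0;
  for (arma::uword k = 0; k < m; ++k) {
    p = p + p * dA.slice(k);
    out.row(k) = p;
  }
  return out;
}

// Coefficients of the wild-bootstrap realization of an Aalen-Johansen
// functional, linear in the per-jump multipliers.
//
// The realization at grid time t_m is sum_e W(e, m) * G_e with
//   W(e, m) = a_e * ( r_{k_e, m}[h_e] - r_{k_e, m}[g_e] ),  k_e <= m,
// where r_{k,m} = P(t_k, t_m) f is the suffix product applied to the
// functional indicator f, and a_e = sqrt(n)/Y_{g_e}(t_{k_e}-) times the
// (0, g_e) entry of P(0, t_{k_e - 1}), supplied precomputed.
//
// ev_k: 1-based event-time index of each jump (sorted nondecreasing);
// grid: 1-based event-time indices at which realizations are required.
// [[Rcpp::export]]
arma::mat aje_wild_coef_cpp(const arma::cube& dA,
                            const arma::vec& f,
                            const arma::ivec& ev_k,
                            const arma::ivec& ev_g,
                            const arma::ivec& ev_h,
                            const arma::vec& a,
                            const arma::ivec& grid) {
  const arma::uword K = dA.n_rows;
  const arma::uword E = ev_k.n_elem, G = grid.n_elem;
  arma::mat W(E, G, arma::fill::zeros);
  arma::mat I(K, K, arma::fill::eye);

  // events grouped by time index: CSR-style offsets over 1..mmax
  arma::uword mmax = dA.n_slices;
  std::vector<std::vector<arma::uword>> by_k(mmax + 1);
  for (arma::uword e = 0; e < E; ++e) by_k[ev_k(e)].push_back(e);

  for (arma::uword gi = 0; gi < G; ++gi) {
    const arma::uword m = grid(gi);
    arma::vec r = f;  // r_{m,m}
    for (arma::uword k = m; k >= 1; --k) {
      for (arma::uword e : by_k[k]) {
        W(e, gi) = a(e) * (r(ev_h(e)) - r(ev_g(e)));
      }
      if (k > 1) r = r + dA.slice(k - 1) * r;  // r_{k-1,m} = (I+dA_k) r_{k,m}
    }
  }
  return W;
}
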