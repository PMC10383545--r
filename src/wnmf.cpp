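#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Weighted non-negative matrix factorization by multiplicative updates.
// Minimizes Q = sum_ij w_ij * (x_ij - (GF)_ij)^2 with w = 1/u^2.
// The Lee-Seung update with per-cell weights is monotone in Q; the full
// Q trace is returned so callers can assert the descent.
//
// Convergence: relative change in Q below `tol` for `n_stable` consecutive
// iterations.
// [[Rcpp::export]]
Rcpp::List wnmf_core(const arma::mat& X, const arma::mat& W,
                     arma::mat G, arma::mat F,
                     const int max_iter, const double tol,
                     const int n_stable) {
  const double eps = 1e-12;
  const mat WX = W % X;

  std::vector<double> q_trace;
  q_trace.reserve(max_iter + 1);

  mat R = G * F;
  double q = accu(W % square(X - R));
  q_trace.push_back(q);

  int stable = 0;
  int iter = 0;
  bool converged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    // G update
    R = G * F;
    G %= (WX * F.t()) / ((W % R) * F.t() + eps);
    // F update
    R = G * F;
    F %= (G.t() * WX) / (G.t() * (W % R) + eps);

    R = G * F;
    double q_new = accu(W % square(X - R));
    q_trace.push_back(q_new);

    double rel = std::fabs(q - q_new) / std::max(q, eps);
    q = q_new;
    if (rel < tol) {
      if (++stable >= n_stable) { converged = true; break; }
    } else {
      stable = 0;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("G") = G,
    Rcpp::Named("F") = F,
    Rcpp::Named("Q") = q,
    Rcpp::Named("q_trace") = q_trace,
    Rcpp::Named("n_iter") = std::min(iter, max_iter),
    Rcpp::Named("converged") = converged);
}
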