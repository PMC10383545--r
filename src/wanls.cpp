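#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fast NNLS on the normal equations (Bro & de Jong): minimize ||y - Zx||^2
// subject to x >= 0, given AtA = Z'Z and Atb = Z'y.
static vec fnnls(const mat& AtA, const vec& Atb) {
  const uword k = Atb.n_elem;
  const double tol = 1e-12 * std::max(1.0, norm(Atb, "inf"));
  vec x(k, fill::zeros);
  uvec passive(k, fill::zeros);   // 0/1 membership
  vec w = Atb;                    // negative gradient at x = 0

  for (uword outer = 0; outer < 30 * k; ++outer) {
    // most violating inactive coordinate
    double wmax = -datum::inf; sword t = -1;
    for (uword i = 0; i < k; ++i) {
      if (!passive(i) && w(i) > wmax) { wmax = w(i); t = i; }
    }
    if (t < 0 || wmax <= tol) break;
    passive(t) = 1;

    for (uword inner = 0; inner < 30 * k; ++inner) {
      uvec P = find(passive == 1);
      vec s_p;
      bool ok = solve(s_p, AtA.submat(P, P), Atb.elem(P),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) s_p = pinv(AtA.submat(P, P)) * Atb.elem(P);
      if (s_p.min() > 0) {
        x.zeros();
        x.elem(P) = s_p;
        break;
      }
      // step back to the boundary and drop the blocking coordinates
      double alpha = datum::inf;
      for (uword ii = 0; ii < P.n_elem; ++ii) {
        if (s_p(ii) <= 0) {
          double xi = x(P(ii));
          double a = xi / (xi - s_p(ii));
          if (a < alpha) alpha = a;
        }
      }
      for (uword ii = 0; ii < P.n_elem; ++ii) {
        x(P(ii)) += alpha * (s_p(ii) - x(P(ii)));
        if (x(P(ii)) <= 1e-14) { x(P(ii)) = 0; passive(P(ii)) = 0; }
      }
      if (!any(passive)) break;
    }
    w = Atb - AtA * x;
  }
  return x;
}

// Alternating exact weighted NNLS for Q = sum_ij w_ij (x_ij - (GF)_ij)^2.
// Each half-sweep solves its block exactly (rows of G against fixed F, then
// columns of F against fixed G), so Q is non-increasing by construction.
// Active-set solutions carry exact zeros, which suits tracer-sparse source
// profiles.
// [[Rcpp::export]]
Rcpp::List wanls_core(const arma::mat& X, const arma::mat& W,
                      arma::mat G, arma::mat F,
                      const int max_iter, const double tol,
                      const int n_stable) {
  const uword n = X.n_rows, m = X.n_cols;
  const uword k = G.n_cols;

  std::vector<double> q_trace;
  double q = accu(W % square(X - G * F));
  q_trace.push_back(q);

  int stable = 0, iter = 0;
  bool converged = false;

  for (iter = 1; iter <= max_iter; ++iter) {
    // update G row-wise: min over g_i >= 0 of sum_j w_ij (x_ij - f_j' g_i)^2
    for (uword i = 0; i < n; ++i) {
      mat Fw = F;                       // K x m
      Fw.each_row() %= W.row(i);
      mat AtA = Fw * F.t();             // K x K
      vec Atb = Fw * X.row(i).t();
      G.row(i) = fnnls(AtA, Atb).t();
    }
    // update F column-wise
    for (uword j = 0; j < m; ++j) {
      mat Gw = G;                       // n x K
      Gw.each_col() %= W.col(j);
      mat AtA = Gw.t() * G;
      vec Atb = Gw.t() * X.col(j);
      F.col(j) = fnnls(symmatu(AtA), Atb);
    }

    double q_new = accu(W % square(X - G * F));
    q_trace.push_back(q_new);
    double rel = std::fabs(q - q_new) / std::max(q, 1e-300);
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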