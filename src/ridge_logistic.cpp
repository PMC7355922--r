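// Ridge-penalized logistic regression (intercept unpenalized) by Newton's
// method with step halving, plus the batched subset-search driver that fits
// one model per (PC subset, cross-validation fold) and returns held-out
// probabilities. The batch path exists purely for speed; it must agree with
// the single-fit path to machine precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double softplus_sum(const vec& eta) {
  double s = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i) {
    double v = eta(i);
    s += (v > 30.0) ? v : std::log1p(std::exp(v));
  }
  return s;
}

// Minimizes -loglik(beta) + reg * ||beta[1:]||^2 over beta (column 0 of X is
// the intercept). Returns beta; sets converged / n_iter / grad_norm.
static vec newton_ridge_logit(const mat& X, const vec& y, double reg,
                              int max_iter, double tol, bool& converged,
                              int& n_iter, double& grad_norm) {
  const uword k = X.n_cols;
  vec pen(k, fill::value(2.0 * reg));
  pen(0) = 0.0;
  vec beta(k, fill::zeros);
  vec eta(X.n_rows, fill::zeros);
  converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    vec p = 1.0 / (1.0 + exp(-eta));
    vec g = X.t() * (p - y) + pen % beta;
    grad_norm = norm(g, "inf");
    if (grad_norm < tol) { converged = true; break; }
    vec w = clamp(p % (1.0 - p), 1e-10, 0.25);
    mat H = X.t() * (X.each_col() % w);
    H.diag() += pen;
    H.diag() += 1e-12;  // guard against exactly singular H at reg = 0
    vec step;
    if (!solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
      step = pinv(H) * g;
    }
    double f0 = softplus_sum(eta) - dot(y, eta) + 0.5 * dot(pen % beta, beta);
    double t = 1.0;
    vec beta_new, eta_new;
    for (int h = 0; h < 40; ++h) {
      beta_new = beta - t * step;
      eta_new = X * beta_new;
      double f1 = softplus_sum(eta_new) - dot(y, eta_new) +
        0.5 * dot(pen % beta_new, beta_new);
      if (f1 <= f0 + 1e-12 * std::abs(f0)) break;
      t *= 0.5;
    }
    beta = beta_new;
    eta = eta_new;
  }
  n_iter = it;
  return beta;
}

// [[Rcpp::export]]
Rcpp::List cpp_ridge_logit(const arma::mat& X, const arma::vec& y, double reg,
                           int max_iter, double tol) {
  bool converged; int n_iter; double grad_norm;
  vec beta = newton_ridge_logit(X, y, reg, max_iter, tol, converged, n_iter,
                                grad_norm);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("n_iter") = n_iter,
                            Rcpp::Named("grad_norm") = grad_norm);
}

// trains/tests: per-fold score matrices (rows = spectra, cols = PCs, no
// intercept column); ys: per-fold 0/1 training labels. subsets: matrix of
// 1-based PC indices padded with zeros, one row per subset; sizes: subset
// sizes. Returns held-out probabilities, subsets x total test spectra (test
// columns ordered fold by fold), and the count of non-converged fits.
// [[Rcpp::export]]
Rcpp::List cpp_subset_search(const Rcpp::List& trains, const Rcpp::List& tests,
                             const Rcpp::List& ys,
                             const arma::imat& subsets,
                             const arma::ivec& sizes,
                             double reg, int max_iter, double tol) {
  const int n_folds = trains.size();
  const uword n_sub = subsets.n_rows;

  uword n_test_total = 0;
  for (int f = 0; f < n_folds; ++f) {
    n_test_total += Rcpp::as<mat>(tests[f]).n_rows;
  }
  mat probs(n_sub, n_test_total);
  uword n_bad = 0;

  uword off = 0;
  for (int f = 0; f < n_folds; ++f) {
    mat Tr = Rcpp::as<mat>(trains[f]);
    mat Te = Rcpp::as<mat>(tests[f]);
    vec y = Rcpp::as<vec>(ys[f]);
    const uword m = Te.n_rows;
    for (uword s = 0; s < n_sub; ++s) {
      const int k = sizes(s);
      mat Xtr(Tr.n_rows, k + 1);
      mat Xte(m, k + 1);
      Xtr.col(0).ones();
      Xte.col(0).ones();
      for (int j = 0; j < k; ++j) {
        const uword col = subsets(s, j) - 1;
        Xtr.col(j + 1) = Tr.col(col);
        Xte.col(j + 1) = Te.col(col);
      }
      bool converged; int n_iter; double grad_norm;
      vec beta = newton_ridge_logit(Xtr, y, reg, max_iter, tol, converged,
                                    n_iter, grad_norm);
      if (!converged) ++n_bad;
      vec eta = Xte * beta;
      probs.submat(s, off, s, off + m - 1) = (1.0 / (1.0 + exp(-eta))).t();
    }
    off += m;
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("n_nonconverged") = (double)n_bad);
}
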