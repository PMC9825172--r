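// EM for a Gaussian mixture with full covariance matrices and a small
// ridge on each covariance for numerical stability. Called from
// fit_mixture(); restarts and initialization are handled in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log N(x | mu, Sigma) for all rows of X, via Cholesky
static vec dmvnorm_log(const mat& X, const rowvec& mu, const mat& Sigma) {
  const uword d = X.n_cols;
  mat R;
  if (!chol(R, Sigma))
    return vec(X.n_rows, fill::value(-datum::inf));
  double logdet = 2.0 * sum(log(R.diag()));
  mat Xc = X.each_row() - mu;
  // solve R^T z = Xc^T  ->  z = R^-T Xc^T; mahalanobis = colSums(z^2)
  mat z = solve(trimatl(R.t()), Xc.t());
  vec maha = sum(square(z), 0).t();
  return -0.5 * (d * std::log(2.0 * datum::pi) + logdet + maha);
}

// [[Rcpp::export(name = ".gmm_em_cpp")]]
Rcpp::List gmm_em_cpp(const arma::mat& X, arma::mat means,
                      arma::cube covs, arma::vec weights,
                      int max_iter, double tol, double ridge_scale) {
  const uword n = X.n_rows, d = X.n_cols, K = means.n_rows;
  mat logdens(n, K);
  double loglik = -datum::inf, prev = -datum::inf;
  bool converged = false;
  int iter = 0;
  mat resp(n, K, fill::zeros);

  for (iter = 0; iter < max_iter; ++iter) {
    // E step
    for (uword k = 0; k < K; ++k)
      logdens.col(k) = std::log(weights(k)) +
        dmvnorm_log(X, means.row(k), covs.slice(k));
    vec mx = max(logdens, 1);
    mat sh = exp(logdens.each_col() - mx);
    vec rs = sum(sh, 1);
    loglik = accu(mx + log(rs));
    resp = sh.each_col() / rs;

    if (std::isfinite(prev) &&
        std::abs(loglik - prev) < tol * (std::abs(prev) + 1.0)) {
      converged = true;
      break;
    }
    prev = loglik;

    // M step
    rowvec nk = sum(resp, 0);              // effective counts
    weights = nk.t() / double(n);
    for (uword k = 0; k < K; ++k) {
      if (nk(k) < 1e-10) continue;         // empty component kept as-is
      rowvec mu = (resp.col(k).t() * X) / nk(k);
      means.row(k) = mu;
      mat Xc = X.each_row() - mu;
      Xc.each_col() %= sqrt(resp.col(k));
      mat S = (Xc.t() * Xc) / nk(k);
      double ridge = ridge_scale * trace(S) / double(d);
      S.diag() += ridge;
      covs.slice(k) = S;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = weights,
    Rcpp::Named("means") = means,
    Rcpp::Named("covs") = covs,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("responsibilities") = resp,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = iter + 1);
}
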