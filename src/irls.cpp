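// Iteratively reweighted least squares for binomial-logit regression.
// Backs the per-code screening loop, where tens of thousands of small
// fits are needed in the bootstrap and simulation suites.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List irls_logit(const arma::mat& X, const arma::vec& y,
                const arma::vec& start,
                double tol = 1e-9, int maxit = 30) {
  const arma::uword p = X.n_cols;
  arma::vec beta = start;
  double dev = std::numeric_limits<double>::infinity();
  bool conv = false;
  arma::mat XtWX(p, p, arma::fill::zeros);
  int it = 0;

  for (it = 0; it < maxit; ++it) {
    arma::vec eta = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    mu = arma::clamp(mu, 1e-10, 1.0 - 1e-10);
    arma::vec w = mu % (1.0 - mu);
    arma::vec z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    XtWX = X.t() * Xw;
    arma::vec Xtwz = X.t() * (w % z);
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtWX, Xtwz,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok) { conv = false; break; }
    beta = beta_new;
    // binomial deviance (y is 0/1)
    arma::vec eta2 = X * beta;
    arma::vec mu2 = arma::clamp(1.0 / (1.0 + arma::exp(-eta2)), 1e-10, 1.0 - 1e-10);
    double dev_new = -2.0 * arma::accu(y % arma::log(mu2) + (1.0 - y) % arma::log(1.0 - mu2));
    if (std::abs(dev - dev_new) / (std::abs(dev_new) + 0.1) < tol) {
      dev = dev_new;
      conv = true;
      break;
    }
    dev = dev_new;
  }

  arma::vec se(p);
  se.fill(NA_REAL);
  arma::mat cov;
  if (arma::inv_sympd(cov, XtWX)) {
    se = arma::sqrt(cov.diag());
  }

  return List::create(
    _["coefficients"] = beta,
    _["se"] = se,
    _["deviance"] = dev,
    _["converged"] = conv,
    _["iterations"] = it + 1);
}
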