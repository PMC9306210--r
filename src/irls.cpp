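#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Newton / iteratively-reweighted-least-squares maximiser of the
// binomial-logit log-likelihood.  `offset` enters the linear predictor
// with a fixed coefficient of one (used by the profile-likelihood code to
// pin a single coefficient); `w` are prior frequency weights.
//
// Convergence: max |score| < tol_score, or relative log-likelihood change
// < tol_ll.  Step-halving guards against overshooting in the Newton step.
// A singular weighted information matrix is reported, not thrown, so the
// caller can attach a machine-readable condition.
// [[Rcpp::export(name = ".irls_logit")]]
List irls_logit(const arma::mat& X, const arma::vec& y,
                const arma::vec& offset, const arma::vec& w,
                const double tol_score, const double tol_ll,
                const int maxit) {
  const arma::uword p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);

  auto loglik = [&](const arma::vec& b) {
    arma::vec eta = offset + X * b;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec mu_c = arma::clamp(mu, 1e-300, 1.0 - 1e-16);
    return arma::dot(w, y % arma::log(mu_c) +
                        (1.0 - y) % arma::log1p(-arma::clamp(mu, 0.0, 1.0 - 1e-16)));
  };

  double ll = loglik(beta);
  bool converged = false, singular = false;
  int iter = 0;

  for (iter = 1; iter <= maxit; ++iter) {
    arma::vec eta = offset + X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec score = X.t() * (w % (y - mu));
    if (arma::abs(score).max() < tol_score) { converged = true; break; }

    arma::vec wvar = w % mu % (1.0 - mu);
    arma::mat XtWX = X.t() * (X.each_col() % wvar);
    arma::vec step;
    const bool ok = arma::solve(step, XtWX, score,
                                arma::solve_opts::no_approx);
    if (!ok) { singular = true; break; }

    // step-halving: accept the first step that does not decrease the
    // log-likelihood (up to 20 halvings)
    double ll_new = R_NegInf;
    arma::vec beta_new = beta;
    double scale = 1.0;
    for (int h = 0; h < 20; ++h) {
      beta_new = beta + scale * step;
      ll_new = loglik(beta_new);
      if (std::isfinite(ll_new) && ll_new >= ll - 1e-12) break;
      scale *= 0.5;
    }
    beta = beta_new;
    const double rel = std::abs(ll_new - ll) / (std::abs(ll_new) + 1e-10);
    ll = ll_new;
    if (rel < tol_ll) { converged = true; break; }
  }

  arma::vec eta = offset + X * beta;
  arma::vec fitted = 1.0 / (1.0 + arma::exp(-eta));
  arma::vec score = X.t() * (w % (y - fitted));

  return List::create(
    _["beta"] = beta,
    _["loglik"] = ll,
    _["fitted"] = fitted,
    _["score"] = score,
    _["iter"] = iter,
    _["converged"] = converged,
    _["singular"] = singular);
}
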