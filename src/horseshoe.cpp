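// Gibbs sampler for horseshoe-prior marker regression:
//   y = 1*mu + X beta + e,  e ~ N(0, sigma2e I)
//   beta_j ~ N(0, lambda_j^2 tau^2 sigma2e),  lambda_j, tau ~ half-Cauchy(0,1)
// Half-Cauchy scales are sampled through inverse-gamma auxiliary variables
// (nu_j, xi), giving closed-form conditionals throughout. The error variance
// carries a scaled-inverse-chi-square prior; scaling the slab by sigma2e
// keeps the conditionals conjugate and the sampler stable.
// Uses R's RNG so set.seed() makes chains exactly reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate); // R::rgamma uses scale
}

// [[Rcpp::export(name = ".horseshoe_gibbs")]]
List horseshoe_gibbs(const arma::vec& y, const arma::mat& X,
                     int n_iter, int burn_in, int thin,
                     double nu0, double s0, bool save_beta) {
  const int n = X.n_rows, p = X.n_cols;
  const arma::vec xtx = arma::sum(arma::square(X), 0).t();

  double mu = arma::mean(y);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec lam2(p, arma::fill::ones), nu(p, arma::fill::ones);
  double tau2 = 1.0, xi = 1.0;
  double sigma2e = arma::var(y);
  if (sigma2e <= 0.0) sigma2e = 1e-8;

  arma::vec r = y - mu; // residual given current state (beta = 0)

  const int n_keep = (n_iter - burn_in) / thin;
  arma::vec mu_draws(n_keep), s2e_draws(n_keep), tau2_draws(n_keep);
  arma::vec beta_mean(p, arma::fill::zeros);
  arma::mat beta_draws;
  if (save_beta) beta_draws.set_size(n_keep, p);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // marker effects, single-site updates with residual maintenance
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) { // monomorphic after centering: no information
        if (beta[j] != 0.0) { r += X.col(j) * beta[j]; beta[j] = 0.0; }
        continue;
      }
      const double prior_prec = 1.0 / (lam2[j] * tau2);
      const double prec = xtx[j] + prior_prec;
      const double rj = arma::dot(X.col(j), r) + xtx[j] * beta[j];
      const double mean_j = rj / prec;
      const double sd_j = std::sqrt(sigma2e / prec);
      const double bnew = R::rnorm(mean_j, sd_j);
      r += X.col(j) * (beta[j] - bnew);
      beta[j] = bnew;
    }
    // local scales and auxiliaries
    for (int j = 0; j < p; ++j) {
      lam2[j] = rinvgamma(1.0, 1.0 / nu[j] + beta[j] * beta[j] / (2.0 * tau2 * sigma2e));
      nu[j] = rinvgamma(1.0, 1.0 + 1.0 / lam2[j]);
    }
    // global scale
    double ssl = 0.0;
    for (int j = 0; j < p; ++j) ssl += beta[j] * beta[j] / lam2[j];
    tau2 = rinvgamma(0.5 * (p + 1.0), 1.0 / xi + ssl / (2.0 * sigma2e));
    xi = rinvgamma(1.0, 1.0 + 1.0 / tau2);
    // intercept (flat prior)
    r += mu; // residual excluding the intercept
    const double mu_new = R::rnorm(arma::mean(r), std::sqrt(sigma2e / n));
    mu = mu_new;
    r -= mu;
    // error variance (scaled-inverse-chi-square prior, slab scaled by sigma2e)
    const double sse = arma::dot(r, r);
    sigma2e = rinvgamma(0.5 * (n + p + nu0), 0.5 * (sse + ssl / tau2 + nu0 * s0));
    if (!std::isfinite(mu) || !std::isfinite(sigma2e) || !beta.is_finite()) {
      stop("horseshoe sampler diverged (non-finite draw) at iteration %d", it);
    }
    if (it > burn_in && (it - burn_in) % thin == 0) {
      mu_draws[kept] = mu;
      s2e_draws[kept] = sigma2e;
      tau2_draws[kept] = tau2;
      beta_mean += beta;
      if (save_beta) beta_draws.row(kept) = beta.t();
      ++kept;
    }
  }
  beta_mean /= std::max(kept, 1);

  List out = List::create(
    _["mu"] = mu_draws, _["sigma2e"] = s2e_draws, _["tau2"] = tau2_draws,
    _["beta_post"] = beta_mean, _["n_kept"] = kept
  );
  if (save_beta) out["beta_draws"] = beta_draws;
  return out;
}
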