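// Compiled numerical core: elastic-net coordinate descent and the Gibbs
// samplers (Bayesian LASSO, multi-trait BayesB). All random draws go
// through R's RNG so set.seed() in R governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Coordinate descent for the unscaled elastic-net objective
//   ||y - X b||^2 + l1 ||b||^2 + l2 ||b||_1
// (l1 multiplies the ridge term, l2 the lasso term). Residuals are
// maintained explicitly; convergence is declared when the largest
// coefficient change in a sweep falls below tol.
// [[Rcpp::export]]
arma::vec enet_cd(const arma::mat& X, const arma::vec& y,
                  double l1, double l2,
                  arma::vec b, int max_iter = 1000, double tol = 1e-10) {
  const int p = X.n_cols;
  arma::vec xx = arma::sum(arma::square(X), 0).t();
  arma::vec r = y - X * b;

  auto update = [&](int j) -> double {
    double bj = b(j);
    double cj = arma::dot(X.col(j), r) + xx(j) * bj;
    double bnew;
    if (xx(j) + l1 <= 0.0) {
      bnew = 0.0;
    } else {
      bnew = soft_threshold(cj, l2 / 2.0) / (xx(j) + l1);
    }
    if (bnew != bj) {
      r += X.col(j) * (bj - bnew);
      b(j) = bnew;
      return std::abs(bnew - bj);
    }
    return 0.0;
  };

  int it = 0;
  while (it < max_iter) {
    // one full sweep over all predictors
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) max_delta = std::max(max_delta, update(j));
    ++it;
    if (max_delta < tol) break;
    // iterate on the active set until it stabilizes, then re-check all
    arma::uvec active = arma::find(b != 0.0);
    while (it < max_iter && active.n_elem > 0) {
      double md = 0.0;
      for (arma::uword a = 0; a < active.n_elem; ++a)
        md = std::max(md, update(active(a)));
      ++it;
      if (md < tol) break;
    }
  }
  return b;
}

// Draw from an inverse-Gaussian(mu, lambda) distribution
// (Michael-Schucany-Haas transform).
static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double zsq = z * z;
  double x = mu + mu * mu * zsq / (2.0 * lambda) -
    (mu / (2.0 * lambda)) *
    std::sqrt(4.0 * mu * lambda * zsq + mu * mu * zsq * zsq);
  if (x <= 0) x = 1e-12;
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Gibbs sampler for the Bayesian LASSO (normal-exponential scale
// mixture with a gamma hyperprior on the squared regularization
// parameter). Single-site updates for the coefficients keep the cost
// linear in p per sweep. Returns posterior means over the kept
// iterations.
// [[Rcpp::export]]
List bl_gibbs(const arma::mat& X, const arma::vec& y,
              int n_iter, int burnin,
              double r_hyper = 1.0, double delta_hyper = 1.0) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec xx = arma::sum(arma::square(X), 0).t();

  arma::vec b(p, arma::fill::zeros);
  arma::vec tau2(p, arma::fill::ones);
  double mu = arma::mean(y);
  double sig2 = arma::var(y);
  if (sig2 <= 0) sig2 = 1e-6;
  double lambda2 = 1.0;

  arma::vec r = y - mu; // residual y - mu - X b (b starts at 0)

  arma::vec b_mean(p, arma::fill::zeros);
  double mu_mean = 0.0, sig2_mean = 0.0, lambda2_mean = 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double mu_old = mu;
    double rbar = arma::mean(r) + mu_old;
    mu = rbar + norm_rand() * std::sqrt(sig2 / n);
    r += mu_old - mu;

    // coefficients, single site
    for (int j = 0; j < p; ++j) {
      double bj = b(j);
      double prec = xx(j) + 1.0 / tau2(j);
      double cj = arma::dot(X.col(j), r) + xx(j) * bj;
      double mean_j = cj / prec;
      double bnew = mean_j + norm_rand() * std::sqrt(sig2 / prec);
      if (bnew != bj) {
        r += X.col(j) * (bj - bnew);
        b(j) = bnew;
      }
    }

    // mixing variances
    for (int j = 0; j < p; ++j) {
      double bsq = std::max(b(j) * b(j), 1e-12);
      double mu_ig = std::sqrt(lambda2 * sig2 / bsq);
      double inv_tau2 = rinvgauss(mu_ig, lambda2);
      tau2(j) = 1.0 / std::max(inv_tau2, 1e-12);
    }

    // residual variance
    double sse = arma::dot(r, r);
    double pen = 0.0;
    for (int j = 0; j < p; ++j) pen += b(j) * b(j) / tau2(j);
    double shape = (n - 1.0 + p) / 2.0;
    double rate = (sse + pen) / 2.0;
    sig2 = rate / R::rgamma(shape, 1.0);
    if (!std::isfinite(sig2) || sig2 <= 0)
      stop("Bayesian LASSO chain diverged (non-finite residual variance)");

    // regularization hyperparameter
    double sum_tau2 = arma::accu(tau2);
    lambda2 = R::rgamma(p + r_hyper, 1.0) / (sum_tau2 / 2.0 + delta_hyper);

    if (it >= burnin) {
      b_mean += b;
      mu_mean += mu;
      sig2_mean += sig2;
      lambda2_mean += lambda2;
      ++kept;
    }
  }
  if (kept == 0) stop("no kept iterations: chain must exceed burn-in");
  b_mean /= kept; mu_mean /= kept; sig2_mean /= kept; lambda2_mean /= kept;
  if (!b_mean.is_finite())
    stop("Bayesian LASSO chain diverged (non-finite coefficients)");
  return List::create(_["b"] = b_mean, _["mu"] = mu_mean,
                      _["sigma2"] = sig2_mean, _["lambda2"] = lambda2_mean,
                      _["kept"] = kept);
}

// Wishart draw via the Bartlett decomposition; scale V, df nu.
static arma::mat rwishart(double nu, const arma::mat& V) {
  const int t = V.n_rows;
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(t, t, arma::fill::zeros);
  for (int i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::mat rinvwishart(double nu, const arma::mat& S) {
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat W = rwishart(nu, Sinv);
  return arma::inv_sympd(arma::symmatu(W));
}

// Gibbs sampler for multi-trait BayesB: each locus carries a vector of
// per-trait inclusion indicators (any pattern admissible) and an effect
// vector with a locus-specific covariance under an inverse-Wishart
// prior; the residual covariance has its own inverse-Wishart prior.
// Indicator and effect are updated jointly per (locus, trait) with the
// effect integrated out of the inclusion odds. The locus covariance is
// carried as its precision P_j = Sigma_j^{-1}: the inverse-Wishart full
// conditional for Sigma_j is a Wishart for P_j whose scale
// (S + a a')^{-1} comes from Sherman-Morrison, so the per-locus update
// needs one small Cholesky and no explicit inversion.
// [[Rcpp::export]]
List mbayesb_gibbs(const arma::mat& X, const arma::mat& Y,
                   int n_iter, int burnin,
                   double pi_incl, double nu_sigma, const arma::mat& S_sigma,
                   double nu_r, const arma::mat& S_r) {
  const int n = X.n_rows, p = X.n_cols, t = Y.n_cols;
  arma::vec xx = arma::sum(arma::square(X), 0).t();

  arma::mat alpha(p, t, arma::fill::zeros); // effects (slab values)
  arma::umat delta(p, t, arma::fill::zeros); // inclusion indicators
  arma::rowvec mu = arma::mean(Y, 0);
  arma::cube Prec(t, t, p); // per-locus effect precision Sigma_j^{-1}
  double prior_div = (nu_sigma > t + 1) ? (nu_sigma - t - 1) : 1.0;
  const arma::mat Sinv_prior = arma::inv_sympd(arma::symmatu(S_sigma));
  for (int j = 0; j < p; ++j) Prec.slice(j) = Sinv_prior * prior_div;
  const arma::mat S_sigma_inv = Sinv_prior;
  arma::mat R = arma::cov(Y);
  R.diag() += 1e-8;

  arma::mat E = Y;
  E.each_row() -= mu; // residuals (B starts at 0)

  arma::mat B_mean(p, t, arma::fill::zeros);
  arma::mat incl_mean(p, t, arma::fill::zeros);
  arma::rowvec mu_mean(t, arma::fill::zeros);
  arma::mat R_mean(t, t, arma::fill::zeros);
  int kept = 0;
  const double log_prior_odds = std::log(pi_incl) - std::log1p(-pi_incl);

  for (int it = 0; it < n_iter; ++it) {
    arma::mat W = arma::inv_sympd(arma::symmatu(R));

    // intercepts: mu | rest ~ N(colmeans(Y - XB), R / n)
    arma::rowvec resid_mean = arma::mean(E, 0) + mu;
    arma::rowvec mu_old = mu;
    arma::vec z(t);
    for (int k = 0; k < t; ++k) z(k) = norm_rand();
    mu = resid_mean + (arma::chol(R, "lower") * z).t() / std::sqrt((double)n);
    E.each_row() += mu_old - mu;

    // loci
    arma::mat Vj(t, t), Lj(t, t), Aj(t, t), LA(t, t);
    arma::vec Sa(t), aj(t);
    for (int j = 0; j < p; ++j) {
      if (xx(j) <= 0) continue;
      const arma::mat& P = Prec.slice(j);
      arma::rowvec u = X.col(j).t() * E; // x_j' E, kept current
      for (int k = 0; k < t; ++k) {
        double beta_old = delta(j, k) ? alpha(j, k) : 0.0;
        double a = xx(j) * W(k, k);
        double c0 = arma::dot(W.row(k), u);
        double cc = a * beta_old + c0;
        // conditional prior of alpha_jk given the other components
        double v0 = 1.0 / P(k, k);
        double m0 = 0.0;
        for (int l = 0; l < t; ++l)
          if (l != k) m0 -= P(k, l) * alpha(j, l);
        m0 *= v0;
        double A = a + 1.0 / v0;
        double M = (cc + m0 / v0) / A;
        double log_odds = log_prior_odds -
          0.5 * std::log(v0 * A) +
          0.5 * (A * M * M - m0 * m0 / v0);
        double pr1 = 1.0 / (1.0 + std::exp(-log_odds));
        unsigned int d_new = (unif_rand() < pr1) ? 1u : 0u;
        double beta_new;
        if (d_new) {
          alpha(j, k) = M + norm_rand() / std::sqrt(A);
          beta_new = alpha(j, k);
        } else {
          alpha(j, k) = m0 + norm_rand() * std::sqrt(v0);
          beta_new = 0.0;
        }
        delta(j, k) = d_new;
        if (beta_new != beta_old) {
          double d = beta_old - beta_new;
          E.col(k) += X.col(j) * d;
          u(k) += xx(j) * d;
        }
      }
      // locus covariance: P_j ~ Wishart(nu + 1, (S + a a')^{-1}), with
      // the scale obtained by the Sherman-Morrison identity
      aj = alpha.row(j).t();
      Sa = S_sigma_inv * aj;
      Vj = S_sigma_inv - (Sa * Sa.t()) / (1.0 + arma::dot(aj, Sa));
      Lj = arma::chol(arma::symmatu(Vj), "lower");
      Aj.zeros();
      for (int i = 0; i < t; ++i) {
        Aj(i, i) = std::sqrt(R::rchisq(nu_sigma + 1.0 - i));
        for (int l = 0; l < i; ++l) Aj(i, l) = norm_rand();
      }
      LA = Lj * Aj;
      Prec.slice(j) = LA * LA.t();
    }

    // residual covariance
    arma::mat SSE = E.t() * E;
    R = rinvwishart(nu_r + n, S_r + SSE);

    if (it >= burnin) {
      arma::mat B = alpha % arma::conv_to<arma::mat>::from(delta);
      B_mean += B;
      incl_mean += arma::conv_to<arma::mat>::from(delta);
      mu_mean += mu;
      R_mean += R;
      ++kept;
    }
  }
  if (kept == 0) stop("no kept iterations: chain must exceed burn-in");
  B_mean /= kept; incl_mean /= kept; mu_mean /= kept; R_mean /= kept;
  if (!B_mean.is_finite())
    stop("mBayesB chain diverged (non-finite coefficients)");
  return List::create(_["B"] = B_mean, _["inclusion"] = incl_mean,
                      _["mu"] = mu_mean, _["R"] = R_mean, _["kept"] = kept);
}
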