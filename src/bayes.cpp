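// Single-site Gibbs samplers for whole-genome regression:
//   method 0 = BayesA   (per-marker scaled-inv-chi^2 effect variances)
//   method 1 = BayesB   (spike-and-slab with fixed null proportion pi)
//   method 2 = BayesCpi (common slab variance, pi sampled from a Beta)
//   method 3 = Bayesian Lasso (Park-Casella hierarchy)
//
// Model: y = 1*mu + W beta + e, W column-centered, flat prior on mu,
// e ~ N(0, sigma_e^2 I).  All draws come from R's RNG stream.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Michael-Schucany-Haas inverse-Gaussian sampler
static double rinvgauss1(double mu, double lambda) {
  if (!(mu > 0.0) || !(lambda > 0.0))
    Rcpp::stop("inverse-Gaussian sampler needs positive parameters");
  double z = R::norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static inline double rscinv_chisq(double df, double scale_sum) {
  // draw from scale_sum / chisq(df)
  return scale_sum / R::rchisq(df);
}

// [[Rcpp::export]]
Rcpp::List bayes_gibbs_cpp(const arma::mat& W, const arma::vec& y,
                           int method, int n_iter, int burn_in, int thin,
                           double pi0, double nu, double S,
                           double nu_e, double S_e,
                           double beta_a, double beta_b,
                           double lasso_r, double lasso_delta,
                           double lambda2_init, bool fix_lambda) {
  const int n = W.n_rows, d = W.n_cols;
  vec cj(d);
  for (int j = 0; j < d; ++j) cj[j] = dot(W.col(j), W.col(j));

  double mu = mean(y);
  vec beta(d, fill::zeros);
  vec e = y - mu;
  double vy = var(y);
  double sigma_e2 = std::max(vy * 0.5, 1e-8);
  double pi = pi0;                       // proportion of NULL markers
  double sigma_b2 = std::max(S, 1e-10);  // common slab variance (Cpi)
  vec sig2(d); sig2.fill(std::max(S, 1e-10)); // per-marker variances (A/B)
  vec tau2(d, fill::ones);               // Lasso local scales
  double lambda2 = lambda2_init;
  ivec delta(d, fill::ones);             // inclusion indicators
  if (method == 1 || method == 2) delta.zeros();

  const int n_saved = (n_iter - burn_in) / thin;
  vec beta_mean(d, fill::zeros);
  vec incl_mean(d, fill::zeros);
  double mu_mean = 0, sigma_e2_mean = 0, pi_mean = 0, lambda2_mean = 0;
  double sigma_b2_mean = 0;
  mat trace(n_saved, 5, fill::zeros);    // sigma_e2, var(Wbeta), pi, lambda2, k
  int saved = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // ---- intercept (flat prior) ----
    e += mu;
    double ebar = mean(e);
    mu = ebar + R::norm_rand() * std::sqrt(sigma_e2 / n);
    e -= mu;

    // ---- marker effects ----
    int k_incl = 0;
    for (int j = 0; j < d; ++j) {
      double c = cj[j];
      if (c <= 0.0) { beta[j] = 0.0; continue; }
      double bold = beta[j];
      double rhs = dot(W.col(j), e) + c * bold;
      double bnew = 0.0;
      if (method == 0) {                                   // BayesA
        double C = c + sigma_e2 / sig2[j];
        bnew = rhs / C + R::norm_rand() * std::sqrt(sigma_e2 / C);
        sig2[j] = rscinv_chisq(nu + 1.0, S * nu + bnew * bnew);
        ++k_incl;
      } else if (method == 1 || method == 2) {             // BayesB / Cpi
        double s2 = (method == 1) ? sig2[j] : sigma_b2;
        double v0 = c * sigma_e2;
        double v1 = v0 + c * c * s2;
        double log_odds = std::log((1.0 - pi) / std::max(pi, 1e-300)) +
          0.5 * (std::log(v0) - std::log(v1)) +
          0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        double p_incl = (pi >= 1.0) ? 0.0 :
          1.0 / (1.0 + std::exp(-log_odds));
        if (R::unif_rand() < p_incl) {
          double C = c + sigma_e2 / s2;
          bnew = rhs / C + R::norm_rand() * std::sqrt(sigma_e2 / C);
          delta[j] = 1; ++k_incl;
        } else {
          bnew = 0.0;
          delta[j] = 0;
        }
        if (method == 1)
          sig2[j] = delta[j] ?
            rscinv_chisq(nu + 1.0, S * nu + bnew * bnew) :
            rscinv_chisq(nu, S * nu);
      } else {                                             // Bayesian Lasso
        double C = c + 1.0 / tau2[j];
        bnew = rhs / C + R::norm_rand() * std::sqrt(sigma_e2 / C);
        double b2 = std::max(bnew * bnew, 1e-12);
        double inv_tau2 = rinvgauss1(std::sqrt(lambda2 * sigma_e2 / b2),
                                     lambda2);
        tau2[j] = 1.0 / std::max(inv_tau2, 1e-12);
        ++k_incl;
      }
      if (bnew != bold) e += W.col(j) * (bold - bnew);
      beta[j] = bnew;
    }

    // ---- hyperparameters ----
    if (method == 2) {
      double ssb = 0.0; int k = 0;
      for (int j = 0; j < d; ++j) if (delta[j]) { ssb += beta[j] * beta[j]; ++k; }
      sigma_b2 = rscinv_chisq(nu + k, S * nu + ssb);
      pi = R::rbeta(beta_a + (double)(d - k), beta_b + (double)k);
    }
    if (method == 3 && !fix_lambda) {
      double sum_tau2 = accu(tau2);
      lambda2 = R::rgamma(lasso_r + d, 1.0 / (lasso_delta + sum_tau2 / 2.0));
    }

    // ---- residual variance ----
    double sse = dot(e, e);
    if (method == 3) {
      double quad = 0.0;
      for (int j = 0; j < d; ++j) quad += beta[j] * beta[j] / tau2[j];
      sigma_e2 = rscinv_chisq((double)n + d + nu_e, sse + quad + nu_e * S_e);
    } else {
      sigma_e2 = rscinv_chisq((double)n + nu_e, sse + nu_e * S_e);
    }
    if (!std::isfinite(sigma_e2))
      Rcpp::stop("residual variance diverged at iteration %d", it);
    sigma_e2 = std::max(sigma_e2, 1e-12);

    // drift control: refresh residual every 1000 cycles
    if (it % 1000 == 0) e = y - mu - W * beta;

    if (it > burn_in && (it - burn_in) % thin == 0) {
      beta_mean += beta;
      for (int j = 0; j < d; ++j) incl_mean[j] += (beta[j] != 0.0) ? 1.0 : 0.0;
      mu_mean += mu; sigma_e2_mean += sigma_e2; pi_mean += pi;
      lambda2_mean += lambda2; sigma_b2_mean += sigma_b2;
      vec g = W * beta;
      trace(saved, 0) = sigma_e2;
      trace(saved, 1) = var(g);
      trace(saved, 2) = pi;
      trace(saved, 3) = lambda2;
      trace(saved, 4) = (double)k_incl;
      ++saved;
    }
  }
  double ns = std::max(saved, 1);
  return Rcpp::List::create(
    Rcpp::Named("beta_mean") = beta_mean / ns,
    Rcpp::Named("incl_prob") = incl_mean / ns,
    Rcpp::Named("mu_mean") = mu_mean / ns,
    Rcpp::Named("sigma_e2_mean") = sigma_e2_mean / ns,
    Rcpp::Named("sigma_b2_mean") = sigma_b2_mean / ns,
    Rcpp::Named("pi_mean") = pi_mean / ns,
    Rcpp::Named("lambda2_mean") = lambda2_mean / ns,
    Rcpp::Named("n_saved") = saved,
    Rcpp::Named("trace") = trace);
}
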