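// Gibbs samplers for whole-genome regression y = mu + W a + e with W the
// column-centered dosage matrix.
//
// gblup_gibbs_cpp: all marker effects share one variance tied to the residual
// variance by a fixed ratio (ridge/GBLUP in the marker parameterization).
//
// bayescpi_gibbs_cpp: spike-and-slab prior; each effect is 0 with probability
// pi, else N(0, sigma_a2); pi has a Uniform(0,1) prior (Beta full
// conditional); sigma_a2 and sigma_e2 have scaled inverse chi-square priors.
//
// Both use R's RNG so set.seed() in R controls the draws.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// scaled inverse chi-square draw: (df * scale) / chisq_df, parameterized by
// the accumulated sum of squares ss and degrees of freedom df
static inline double rinvchisq(double ss, double df) {
  return ss / R::rchisq(df);
}

// [[Rcpp::export]]
List gblup_gibbs_cpp(const arma::vec& y, const arma::mat& W, double lambda,
                     int n_iter, int burn_in, int thin,
                     double fixed_sigma_e2) {
  const int n = y.n_elem, m = W.n_cols;
  arma::vec wtw(m);
  for (int j = 0; j < m; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));

  double mu = arma::mean(y);
  double sigma_e2 = (fixed_sigma_e2 > 0.0) ? fixed_sigma_e2
                                           : arma::var(y) * 0.5 + 1e-12;
  arma::vec a(m, arma::fill::zeros);
  arma::vec e = y - mu;

  arma::vec a_sum(m, arma::fill::zeros), a_sumsq(m, arma::fill::zeros);
  double mu_sum = 0.0, se_sum = 0.0;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // overall mean
    e += mu;
    double mnew = arma::mean(e) + R::rnorm(0.0, std::sqrt(sigma_e2 / n));
    mu = mnew;
    e -= mu;
    // marker effects, single site
    for (int j = 0; j < m; ++j) {
      if (wtw(j) <= 0.0) continue;
      double aj = a(j);
      double rhs = arma::dot(W.col(j), e) + wtw(j) * aj;
      double Cj = wtw(j) + lambda;
      double anew = rhs / Cj + R::rnorm(0.0, std::sqrt(sigma_e2 / Cj));
      e += W.col(j) * (aj - anew);
      a(j) = anew;
    }
    // residual variance (marker variance is sigma_e2 / lambda)
    if (fixed_sigma_e2 <= 0.0) {
      double ss = arma::dot(e, e) + lambda * arma::dot(a, a);
      sigma_e2 = rinvchisq(ss, (double)(n + m));
    }
    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++kept;
      a_sum += a; a_sumsq += arma::square(a);
      mu_sum += mu; se_sum += sigma_e2;
    }
  }
  arma::vec a_mean = a_sum / kept;
  arma::vec a_sd = arma::sqrt(arma::clamp(a_sumsq / kept - arma::square(a_mean),
                                          0.0, arma::datum::inf));
  return List::create(_["mu"] = mu_sum / kept,
                      _["a_post_mean"] = a_mean,
                      _["a_post_sd"] = a_sd,
                      _["sigma_e2_prime"] = se_sum / kept,
                      _["n_kept"] = kept);
}

// [[Rcpp::export]]
List bayescpi_gibbs_cpp(const arma::vec& y, const arma::mat& W,
                        int n_iter, int burn_in, int thin,
                        double pi_init, double nu_a, double s_a,
                        double nu_e, double s_e,
                        double fix_pi, double fixed_sigma_a2,
                        double fixed_sigma_e2) {
  const int n = y.n_elem, m = W.n_cols;
  arma::vec wtw(m);
  for (int j = 0; j < m; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));

  double mu = arma::mean(y);
  double pi = (fix_pi >= 0.0) ? fix_pi : pi_init;
  double sigma_a2 = (fixed_sigma_a2 > 0.0) ? fixed_sigma_a2
                                           : nu_a * s_a / (nu_a - 2.0);
  double sigma_e2 = (fixed_sigma_e2 > 0.0) ? fixed_sigma_e2
                                           : arma::var(y) * 0.5 + 1e-12;
  arma::vec a(m, arma::fill::zeros);
  arma::ivec delta(m, arma::fill::zeros);
  arma::vec e = y - mu;

  arma::vec a_sum(m, arma::fill::zeros), a_sumsq(m, arma::fill::zeros);
  arma::vec incl_sum(m, arma::fill::zeros);
  double mu_sum = 0.0, pi_sum = 0.0, sa_sum = 0.0, se_sum = 0.0;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    e += mu;
    mu = arma::mean(e) + R::rnorm(0.0, std::sqrt(sigma_e2 / n));
    e -= mu;

    int m_in = 0;
    double ssa = 0.0;
    for (int j = 0; j < m; ++j) {
      double aj = a(j);
      if (wtw(j) <= 0.0) { a(j) = 0.0; delta(j) = 0; continue; }
      double rhs = arma::dot(W.col(j), e) + wtw(j) * aj;
      double v0 = wtw(j) * sigma_e2;
      double v1 = wtw(j) * wtw(j) * sigma_a2 + v0;
      // log Bayes factor for inclusion
      double logbf = -0.5 * (std::log(v1) - std::log(v0))
                     - 0.5 * rhs * rhs * (1.0 / v1 - 1.0 / v0);
      double p1;
      if (pi >= 1.0) p1 = 0.0;
      else if (pi <= 0.0) p1 = 1.0;
      else {
        double logodds = std::log(1.0 - pi) - std::log(pi) + logbf;
        p1 = 1.0 / (1.0 + std::exp(-logodds));
      }
      double anew = 0.0;
      if (R::runif(0.0, 1.0) < p1) {
        double Cj = wtw(j) + sigma_e2 / sigma_a2;
        anew = rhs / Cj + R::rnorm(0.0, std::sqrt(sigma_e2 / Cj));
        delta(j) = 1; ++m_in; ssa += anew * anew;
      } else {
        delta(j) = 0;
      }
      if (anew != aj) e += W.col(j) * (aj - anew);
      a(j) = anew;
    }
    if (fixed_sigma_a2 <= 0.0)
      sigma_a2 = rinvchisq(ssa + nu_a * s_a, nu_a + (double)m_in);
    if (fixed_sigma_e2 <= 0.0)
      sigma_e2 = rinvchisq(arma::dot(e, e) + nu_e * s_e, nu_e + (double)n);
    if (fix_pi < 0.0)
      pi = R::rbeta((double)(m - m_in) + 1.0, (double)m_in + 1.0);

    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++kept;
      a_sum += a; a_sumsq += arma::square(a);
      for (int j = 0; j < m; ++j) incl_sum(j) += delta(j);
      mu_sum += mu; pi_sum += pi; sa_sum += sigma_a2; se_sum += sigma_e2;
    }
  }
  arma::vec a_mean = a_sum / kept;
  arma::vec a_sd = arma::sqrt(arma::clamp(a_sumsq / kept - arma::square(a_mean),
                                          0.0, arma::datum::inf));
  return List::create(_["mu"] = mu_sum / kept,
                      _["a_post_mean"] = a_mean,
                      _["a_post_sd"] = a_sd,
                      _["inclusion_prob"] = incl_sum / kept,
                      _["pi_post_mean"] = pi_sum / kept,
                      _["sigma_a2"] = sa_sum / kept,
                      _["sigma_e2_prime"] = se_sum / kept,
                      _["n_kept"] = kept);
}
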