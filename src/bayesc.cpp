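#include <Rcpp.h>
using namespace Rcpp;

// BayesC-pi Gibbs sampler.
//
// Model: y = mu + sum_j W_j beta_j delta_j + e, with per-marker inclusion
// indicators delta_j, a common effect variance sigma2_b ~ scaled-inv-chi2,
// residual sigma2_e ~ scaled-inv-chi2, and a uniform prior on the
// inclusion proportion.  pi is reported as the proportion of markers with
// a ZERO effect (the sparsity), so a polygenic trait gives small pi and a
// sparse one gives pi near 1.  Uses R's RNG, so set.seed() in R makes the
// chain reproducible.
//
// [[Rcpp::export]]
List bayesc_gibbs(NumericVector y, NumericMatrix W, int n_iter, int burn,
                  int thin, double nu_b, double s_b, double nu_e,
                  double s_e) {
  int n = y.size();
  int m = W.ncol();
  if (W.nrow() != n) stop("W/y dimension mismatch");

  // precompute column cross-products
  std::vector<double> cj(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, j) * W(i, j);
    cj[j] = s;
  }

  double mu = mean(y);
  std::vector<double> beta(m, 0.0);
  std::vector<int> incl(m, 0);
  double sigma2_e = s_e;
  double sigma2_b = s_b;
  double pi_in = 0.5;  // inclusion probability

  // residual e = y - mu - W beta (all beta start at 0)
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> beta_post(m, 0.0), pip(m, 0.0);
  double mu_post = 0.0, pi_zero_post = 0.0, s2b_post = 0.0, s2e_post = 0.0;
  int n_samp = 0;
  std::vector<double> pi_trace;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double e_sum = 0.0;
    for (int i = 0; i < n; ++i) e_sum += e[i] + mu;
    double mu_new = R::rnorm(e_sum / n, std::sqrt(sigma2_e / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // marker effects with spike-and-slab
    int k_in = 0;
    double ssq_beta = 0.0;
    double log_odds_prior = std::log(pi_in) - std::log(1.0 - pi_in);
    for (int j = 0; j < m; ++j) {
      if (cj[j] <= 0.0) { beta[j] = 0.0; incl[j] = 0; continue; }
      // rhs on the full conditional scale: W_j' (e + W_j beta_j)
      double rj = 0.0;
      if (incl[j]) {
        for (int i = 0; i < n; ++i) rj += W(i, j) * e[i];
        rj += cj[j] * beta[j];
      } else {
        for (int i = 0; i < n; ++i) rj += W(i, j) * e[i];
      }
      double v1 = cj[j] * cj[j] * sigma2_b + cj[j] * sigma2_e;
      double v0 = cj[j] * sigma2_e;
      double log_bf = 0.5 * std::log(v0 / v1) +
        0.5 * rj * rj * (1.0 / v0 - 1.0 / v1);
      double log_odds = log_odds_prior + log_bf;
      double p_in = 1.0 / (1.0 + std::exp(-log_odds));
      double old_beta = incl[j] ? beta[j] : 0.0;
      if (R::unif_rand() < p_in) {
        double cpost = cj[j] + sigma2_e / sigma2_b;
        double bmean = rj / cpost;
        double bnew = R::rnorm(bmean, std::sqrt(sigma2_e / cpost));
        double diff = bnew - old_beta;
        if (diff != 0.0)
          for (int i = 0; i < n; ++i) e[i] -= W(i, j) * diff;
        beta[j] = bnew;
        incl[j] = 1;
        ++k_in;
        ssq_beta += bnew * bnew;
      } else {
        if (old_beta != 0.0)
          for (int i = 0; i < n; ++i) e[i] += W(i, j) * old_beta;
        beta[j] = 0.0;
        incl[j] = 0;
      }
    }

    // common effect variance (scaled-inverse-chi-square)
    sigma2_b = (ssq_beta + nu_b * s_b) / R::rchisq(nu_b + k_in);
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2_e = (sse + nu_e * s_e) / R::rchisq(nu_e + n);
    if (!std::isfinite(sigma2_e) || !std::isfinite(sigma2_b))
      stop("divergent chain: non-finite variance sample");
    // inclusion proportion, uniform prior
    pi_in = R::rbeta(1.0 + k_in, 1.0 + m - k_in);
    if (pi_in < 1e-6) pi_in = 1e-6;
    if (pi_in > 1.0 - 1e-6) pi_in = 1.0 - 1e-6;

    if (it >= burn && ((it - burn) % thin == 0)) {
      ++n_samp;
      for (int j = 0; j < m; ++j) {
        beta_post[j] += beta[j];
        pip[j] += incl[j];
      }
      mu_post += mu;
      pi_zero_post += 1.0 - pi_in;
      s2b_post += sigma2_b;
      s2e_post += sigma2_e;
      pi_trace.push_back(1.0 - pi_in);
    }
  }
  if (n_samp == 0) stop("no posterior samples: check iter/burn/thin");
  NumericVector beta_out(m), pip_out(m);
  for (int j = 0; j < m; ++j) {
    beta_out[j] = beta_post[j] / n_samp;
    pip_out[j] = pip[j] / n_samp;
  }
  return List::create(
    _["mu"] = mu_post / n_samp,
    _["beta"] = beta_out,
    _["pip"] = pip_out,
    _["pi_zero"] = pi_zero_post / n_samp,
    _["pi_trace"] = wrap(pi_trace),
    _["sigma2_b"] = s2b_post / n_samp,
    _["sigma2_e"] = s2e_post / n_samp,
    _["n_samples"] = n_samp);
}
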