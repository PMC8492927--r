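#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for BayesC whole-genome regression.
//
//   y = W b + sum_j m_j alpha_j delta_j + e
//   alpha_j | delta_j = 1 ~ N(0, sigma_a2), delta_j ~ Bern(pi)
//   sigma_a2, sigma_e2 ~ scaled-inv-chi2(df, S); pi ~ Beta(c*pi0, c*(1-pi0))
//
// M must be column-centered by the caller (training means); W carries the
// intercept. Uses R's RNG so chains are reproducible under set.seed().
//
// [[Rcpp::export(name = ".bayesc_gibbs")]]
List bayesc_gibbs(NumericVector y, NumericMatrix W, NumericMatrix M,
                  int n_iter, int burn_in, int thin,
                  double df_e, double S_e, double df_a, double S_a,
                  double pi0, double pi_counts,
                  bool fix_pi, double pi_fixed,
                  bool fix_var, double sigma_a2_fixed,
                  double sigma_e2_fixed) {
  const int n = y.size(), L = M.ncol(), p = W.ncol();

  // precompute column cross-products
  std::vector<double> m2(L), w2(p);
  for (int j = 0; j < L; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += M(i, j) * M(i, j);
    m2[j] = s;
  }
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += W(i, k) * W(i, k);
    w2[k] = s;
  }

  std::vector<double> alpha(L, 0.0), b(p, 0.0), e(n);
  std::vector<int> delta(L, 0);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  double sigma_a2 = fix_var ? sigma_a2_fixed : S_a;
  double sigma_e2 = fix_var ? sigma_e2_fixed : S_e;
  double pi = fix_pi ? pi_fixed : pi0;

  std::vector<double> a_sum(L, 0.0), d_sum(L, 0.0), b_sum(p, 0.0);
  std::vector<double> sa_tr, se_tr, pi_tr;
  int nsave = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects, one column at a time (p is small)
    for (int k = 0; k < p; ++k) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += W(i, k) * (e[i] + W(i, k) * b[k]);
      double mean = rhs / w2[k];
      double bnew = R::rnorm(mean, std::sqrt(sigma_e2 / w2[k]));
      double dlt = bnew - b[k];
      for (int i = 0; i < n; ++i) e[i] -= W(i, k) * dlt;
      b[k] = bnew;
    }

    // markers: spike-and-slab single-site updates
    int n_in = 0;
    double ssa = 0.0;
    const double lambda = sigma_e2 / sigma_a2;
    const double logit_pi = std::log(pi) - std::log1p(-pi);
    for (int j = 0; j < L; ++j) {
      double rhs = 0.0;
      if (alpha[j] != 0.0) {
        for (int i = 0; i < n; ++i) rhs += M(i, j) * (e[i] + M(i, j) * alpha[j]);
      } else {
        for (int i = 0; i < n; ++i) rhs += M(i, j) * e[i];
      }
      const double C = m2[j] + lambda;
      // log Bayes factor of inclusion vs exclusion
      const double logBF = 0.5 * (std::log(lambda) - std::log(C)) +
        0.5 * rhs * rhs / (sigma_e2 * C);
      const double logodds = logBF + logit_pi;
      const double pin = 1.0 / (1.0 + std::exp(-logodds));
      const double u = R::unif_rand();
      double anew = 0.0;
      int dnew = 0;
      if (u < pin) {
        dnew = 1;
        anew = R::rnorm(rhs / C, std::sqrt(sigma_e2 / C));
      }
      if (anew != alpha[j]) {
        const double dlt = anew - alpha[j];
        for (int i = 0; i < n; ++i) e[i] -= M(i, j) * dlt;
        alpha[j] = anew;
      }
      delta[j] = dnew;
      if (dnew) { ++n_in; ssa += anew * anew; }
    }

    if (!fix_var) {
      sigma_a2 = (ssa + df_a * S_a) / R::rchisq(df_a + n_in);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = (sse + df_e * S_e) / R::rchisq(df_e + n);
    }
    if (!fix_pi) {
      pi = R::rbeta(pi_counts * pi0 + n_in,
                    pi_counts * (1.0 - pi0) + (L - n_in));
      if (pi <= 1e-12) pi = 1e-12;
      if (pi >= 1.0 - 1e-12) pi = 1.0 - 1e-12;
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++nsave;
      for (int j = 0; j < L; ++j) {
        a_sum[j] += alpha[j];
        d_sum[j] += delta[j];
      }
      for (int k = 0; k < p; ++k) b_sum[k] += b[k];
      sa_tr.push_back(sigma_a2);
      se_tr.push_back(sigma_e2);
      pi_tr.push_back(pi);
    }
  }

  NumericVector am(L), dm(L), bm(p);
  for (int j = 0; j < L; ++j) { am[j] = a_sum[j] / nsave; dm[j] = d_sum[j] / nsave; }
  for (int k = 0; k < p; ++k) bm[k] = b_sum[k] / nsave;
  return List::create(_["alpha"] = am, _["inclusion_prob"] = dm,
                      _["b"] = bm, _["sigma_a2_trace"] = wrap(sa_tr),
                      _["sigma_e2_trace"] = wrap(se_tr),
                      _["pi_trace"] = wrap(pi_tr), _["n_saved"] = nsave);
}
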