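#include <Rcpp.h>
using namespace Rcpp;

// Hierarchical Bayesian estimation for one group x one model.
//
// Non-centered parameterization on an unconstrained scale:
//   raw_ik = mu_k + sigma_k * z_ik,   z_ik ~ Normal(0, 1)
//   mu_k ~ Normal(0, 1),  sigma_k ~ half-Normal(0, 0.2)
// Subject parameters are obtained by squashing raw values onto their support:
// learning rates / decays via inverse-logit, beta via 5 * inverse-logit,
// alpha via inverse-logit - 0.5.
//
// Sampling is adaptive Metropolis-within-Gibbs: scalar random-walk updates of
// each z_ik, mu_k and log(sigma_k), with per-coordinate step sizes tuned
// toward 0.44 acceptance during warmup only. Uses R's RNG so results are
// reproducible via set.seed().

static const double LOG_FLOOR = -27.631021115928547; // log(1e-12)

static inline int n_learn_params(int model) {
  return (model == 1 || model == 2) ? 1 : 2;
}

static inline double inv_logit(double x) {
  if (x > 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double transform_param(int k, int K, double raw) {
  double il = inv_logit(raw);
  if (k == K - 2) return 5.0 * il;        // beta
  if (k == K - 1) return il - 0.5;        // alpha
  return il;                              // rates / decays
}

// sequence log-likelihood for one subject under transformed params th[K]
static double subj_loglik(int model, const double *th, const int *choice,
                          const double *outcome, int T) {
  int L = n_learn_params(model);
  double beta = th[L], alpha = th[L + 1];
  double V[2] = {0.0, 0.0};
  double n[2] = {1.0, 1.0};
  double tot = 0.0;
  for (int t = 0; t < T; ++t) {
    double x = beta * (alpha - (V[0] - V[1]));
    double pA = (x > 0.0) ? std::exp(-x) / (1.0 + std::exp(-x))
                          : 1.0 / (1.0 + std::exp(x));
    double p = (choice[t] == 0) ? pA : 1.0 - pA;
    tot += (p < 1e-12) ? LOG_FLOOR : std::log(p);
    int c = choice[t], nc = 1 - c;
    double O = outcome[t];
    switch (model) {
    case 1:
      V[c] += th[0] * (O - V[c]);
      break;
    case 2:
      V[c]  += th[0] * (O - V[c]);
      V[nc] += th[0] * (-O - V[nc]);
      break;
    case 3: {
      double eta = (O > 0.0) ? th[0] : th[1];
      V[c] += eta * (O - V[c]);
      break;
    }
    case 4: {
      double nprev = n[c];
      n[c] = nprev * th[1] + 1.0;
      V[c] = (V[c] * th[0] * nprev + O) / n[c];
      break;
    }
    }
  }
  return tot;
}

struct GroupData {
  int model, N, T, K, L;
  const int *choices;      // N x T, column-major from R -> use (t * N + i)
  const double *outcomes;
  double sigma_prior_sd;
};

static void make_theta(const GroupData &g, const double *mu,
                       const double *sigma, const double *z, int i,
                       double *th) {
  for (int k = 0; k < g.K; ++k)
    th[k] = transform_param(k, g.K, mu[k] + sigma[k] * z[i * g.K + k]);
}

static double loglik_i(const GroupData &g, const double *mu,
                       const double *sigma, const double *z, int i) {
  std::vector<double> th(g.K);
  make_theta(g, mu, sigma, z, i, &th[0]);
  std::vector<int> ch(g.T);
  std::vector<double> oc(g.T);
  for (int t = 0; t < g.T; ++t) {
    ch[t] = g.choices[t * g.N + i];
    oc[t] = g.outcomes[t * g.N + i];
  }
  return subj_loglik(g.model, &th[0], &ch[0], &oc[0], g.T);
}

// [[Rcpp::export]]
List cpp_fit_group(int model, IntegerMatrix choices, NumericMatrix outcomes,
                   int n_warmup, int n_iter, int n_chains,
                   double sigma_prior_sd) {
  GroupData g;
  g.model = model;
  g.N = choices.nrow();
  g.T = choices.ncol();
  g.L = n_learn_params(model);
  g.K = g.L + 2;
  g.choices = &choices[0];
  g.outcomes = &outcomes[0];
  g.sigma_prior_sd = sigma_prior_sd;
  const int N = g.N, K = g.K;

  NumericVector mu_draws((R_xlen_t)n_iter * n_chains * K);
  NumericVector sigma_draws((R_xlen_t)n_iter * n_chains * K);
  NumericVector theta_draws((R_xlen_t)n_iter * n_chains * N * K);

  for (int ch = 0; ch < n_chains; ++ch) {
    // jittered initial values
    std::vector<double> mu(K), ls(K), z((size_t)N * K);
    for (int k = 0; k < K; ++k) {
      mu[k] = 0.1 * norm_rand();
      ls[k] = std::log(0.2) + 0.1 * norm_rand();
    }
    for (size_t j = 0; j < z.size(); ++j) z[j] = 0.1 * norm_rand();
    std::vector<double> sigma(K);
    for (int k = 0; k < K; ++k) sigma[k] = std::exp(ls[k]);

    // cached per-subject log-likelihoods
    std::vector<double> ll(N);
    for (int i = 0; i < N; ++i) ll[i] = loglik_i(g, &mu[0], &sigma[0], &z[0], i);

    // adaptive step sizes: one per z coordinate, plus mu and ls coordinates
    std::vector<double> step_z((size_t)N * K, 0.5), step_mu(K, 0.2),
        step_ls(K, 0.2);
    std::vector<int> acc_z((size_t)N * K, 0), acc_mu(K, 0), acc_ls(K, 0);
    int batch = 0, batch_len = 50;

    int total_sweeps = n_warmup + n_iter;
    for (int sw = 0; sw < total_sweeps; ++sw) {
      // --- per-subject z updates ---
      for (int i = 0; i < N; ++i) {
        for (int k = 0; k < K; ++k) {
          size_t idx = (size_t)i * K + k;
          double z_old = z[idx];
          double z_new = z_old + step_z[idx] * norm_rand();
          z[idx] = z_new;
          double ll_new = loglik_i(g, &mu[0], &sigma[0], &z[0], i);
          double delta = ll_new - ll[i] - 0.5 * (z_new * z_new - z_old * z_old);
          if (std::log(unif_rand()) < delta) {
            ll[i] = ll_new;
            ++acc_z[idx];
          } else {
            z[idx] = z_old;
          }
        }
      }
      // --- group-level mu updates ---
      for (int k = 0; k < K; ++k) {
        double mu_old = mu[k];
        double mu_new = mu_old + step_mu[k] * norm_rand();
        mu[k] = mu_new;
        std::vector<double> ll_new(N);
        double dll = 0.0;
        for (int i = 0; i < N; ++i) {
          ll_new[i] = loglik_i(g, &mu[0], &sigma[0], &z[0], i);
          dll += ll_new[i] - ll[i];
        }
        double delta = dll - 0.5 * (mu_new * mu_new - mu_old * mu_old);
        if (std::log(unif_rand()) < delta) {
          ll = ll_new;
          ++acc_mu[k];
        } else {
          mu[k] = mu_old;
        }
      }
      // --- group-level log-sigma updates (half-Normal prior + Jacobian) ---
      for (int k = 0; k < K; ++k) {
        double ls_old = ls[k], s_old = sigma[k];
        double ls_new = ls_old + step_ls[k] * norm_rand();
        double s_new = std::exp(ls_new);
        ls[k] = ls_new;
        sigma[k] = s_new;
        std::vector<double> ll_new(N);
        double dll = 0.0;
        for (int i = 0; i < N; ++i) {
          ll_new[i] = loglik_i(g, &mu[0], &sigma[0], &z[0], i);
          dll += ll_new[i] - ll[i];
        }
        double sp = g.sigma_prior_sd;
        double delta = dll -
            0.5 * (s_new * s_new - s_old * s_old) / (sp * sp) +
            (ls_new - ls_old); // Jacobian of exp transform
        if (std::log(unif_rand()) < delta) {
          ll = ll_new;
          ++acc_ls[k];
        } else {
          ls[k] = ls_old;
          sigma[k] = s_old;
        }
      }

      // --- warmup-only step-size adaptation toward 0.44 acceptance ---
      if (sw < n_warmup && (sw + 1) % batch_len == 0) {
        ++batch;
        double gain = std::min(0.25, 1.0 / std::sqrt((double)batch));
        for (size_t j = 0; j < step_z.size(); ++j) {
          double rate = (double)acc_z[j] / batch_len;
          step_z[j] *= std::exp(gain * (rate - 0.44));
          acc_z[j] = 0;
        }
        for (int k = 0; k < K; ++k) {
          double rm = (double)acc_mu[k] / batch_len;
          step_mu[k] *= std::exp(gain * (rm - 0.44));
          acc_mu[k] = 0;
          double rl = (double)acc_ls[k] / batch_len;
          step_ls[k] *= std::exp(gain * (rl - 0.44));
          acc_ls[k] = 0;
        }
      }

      // --- store post-warmup draws ---
      if (sw >= n_warmup) {
        int it = sw - n_warmup;
        for (int k = 0; k < K; ++k) {
          R_xlen_t base = (R_xlen_t)it + (R_xlen_t)n_iter * (ch + n_chains * k);
          mu_draws[base] = mu[k];
          sigma_draws[base] = sigma[k];
        }
        std::vector<double> th(K);
        for (int i = 0; i < N; ++i) {
          make_theta(g, &mu[0], &sigma[0], &z[0], i, &th[0]);
          for (int k = 0; k < K; ++k) {
            R_xlen_t base = (R_xlen_t)it +
              (R_xlen_t)n_iter * (ch + (R_xlen_t)n_chains * (i + (R_xlen_t)N * k));
            theta_draws[base] = th[k];
          }
        }
      }
    }
  }

  mu_draws.attr("dim") = IntegerVector::create(n_iter, n_chains, K);
  sigma_draws.attr("dim") = IntegerVector::create(n_iter, n_chains, K);
  theta_draws.attr("dim") = IntegerVector::create(n_iter, n_chains, N, K);
  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws,
                      _["theta"] = theta_draws);
}
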