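#include <Rcpp.h>
using namespace Rcpp;

// Model codes shared with R/models.R: 1 = RW, 2 = CU, 3 = RP, 4 = EWA_DL.
// Parameter layout: learning parameter(s) first, then beta, then alpha.
//   RW/CU : (eta, beta, alpha)
//   RP    : (eta_rew, eta_pun, beta, alpha)
//   EWA_DL: (phi, rho, beta, alpha)

static const double LOG_FLOOR = -27.631021115928547; // log(1e-12)

struct RLState {
  double V[2];
  double n[2];
};

static inline void rl_init(RLState &s) {
  s.V[0] = s.V[1] = 0.0;
  s.n[0] = s.n[1] = 1.0;
}

// c is the chosen stimulus (0 = A, 1 = B); lp points at the learning params
static inline void rl_update(int model, RLState &s, int c, double O,
                             const double *lp) {
  int nc = 1 - c;
  switch (model) {
  case 1: // Rescorla-Wagner: chosen value only
    s.V[c] += lp[0] * (O - s.V[c]);
    break;
  case 2: // counterfactual update: unchosen gets the negated outcome
    s.V[c]  += lp[0] * (O - s.V[c]);
    s.V[nc] += lp[0] * (-O - s.V[nc]);
    break;
  case 3: { // reward-punishment: rate depends on outcome sign
    double eta = (O > 0.0) ? lp[0] : lp[1];
    s.V[c] += eta * (O - s.V[c]);
    break;
  }
  case 4: { // EWA dynamic learning rate: experience weight n, payoff decay phi
    double nprev = s.n[c];
    s.n[c] = nprev * lp[1] + 1.0;
    s.V[c] = (s.V[c] * lp[0] * nprev + O) / s.n[c];
    break;
  }
  }
}

// p(choose A) = 1 / (1 + exp(beta * (alpha - (V_A - V_B)))), overflow-safe
static inline double rl_p_A(const RLState &s, double beta, double alpha) {
  double x = beta * (alpha - (s.V[0] - s.V[1]));
  if (x > 0.0) {
    double e = std::exp(-x);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(x));
}

static inline int n_learn_params(int model) {
  return (model == 1 || model == 2) ? 1 : 2;
}

static inline double safe_log(double p) {
  return (p < 1e-12) ? LOG_FLOOR : std::log(p);
}

// Per-trial log-probabilities of the recorded choices under one parameter set
// [[Rcpp::export]]
NumericVector cpp_seq_loglik(int model, NumericVector params,
                             IntegerVector choice, NumericVector outcome) {
  int T = choice.size();
  int L = n_learn_params(model);
  double beta = params[L], alpha = params[L + 1];
  const double *lp = &params[0];
  NumericVector ll(T);
  RLState s;
  rl_init(s);
  for (int t = 0; t < T; ++t) {
    double pA = rl_p_A(s, beta, alpha);
    double p = (choice[t] == 0) ? pA : 1.0 - pA;
    ll[t] = safe_log(p);
    rl_update(model, s, choice[t], outcome[t], lp);
  }
  return ll;
}

// Total sequence log-likelihood for each row of a draws x params matrix
// [[Rcpp::export]]
NumericVector cpp_loglik_draws(int model, NumericMatrix theta,
                               IntegerVector choice, NumericVector outcome) {
  int S = theta.nrow(), T = choice.size();
  int L = n_learn_params(model);
  NumericVector out(S);
  std::vector<double> par(L + 2);
  for (int d = 0; d < S; ++d) {
    for (int k = 0; k < L + 2; ++k) par[k] = theta(d, k);
    double beta = par[L], alpha = par[L + 1];
    RLState s;
    rl_init(s);
    double tot = 0.0;
    for (int t = 0; t < T; ++t) {
      double pA = rl_p_A(s, beta, alpha);
      double p = (choice[t] == 0) ? pA : 1.0 - pA;
      tot += safe_log(p);
      rl_update(model, s, choice[t], outcome[t], &par[0]);
    }
    out[d] = tot;
  }
  return out;
}

// Simulate one agent on a fixed feedback schedule. The stimulus chosen on
// trial 1 defines the acquisition-phase correct stimulus; it flips at
// `reversal` (1-based first reversal trial). Feedback is anti-correlated:
// the incorrect choice receives the negated scheduled outcome.
// [[Rcpp::export]]
List cpp_simulate_agent(int model, NumericVector params,
                        IntegerVector sched, int reversal) {
  int T = sched.size();
  int L = n_learn_params(model);
  double beta = params[L], alpha = params[L + 1];
  const double *lp = &params[0];
  IntegerVector choice(T), correct(T);
  NumericVector outcome(T);
  RLState s;
  rl_init(s);
  int correct_acq = -1;
  for (int t = 0; t < T; ++t) {
    double pA = rl_p_A(s, beta, alpha);
    int c = (unif_rand() < pA) ? 0 : 1;
    if (t == 0) correct_acq = c;
    int corr = (t + 1 < reversal) ? correct_acq : 1 - correct_acq;
    double O = (c == corr) ? (double)sched[t] : -(double)sched[t];
    choice[t] = c;
    correct[t] = corr;
    outcome[t] = O;
    rl_update(model, s, c, O, lp);
  }
  return List::create(_["choice"] = choice, _["outcome"] = outcome,
                      _["correct"] = correct);
}

// Mean choice accuracy (choice == currently-correct stimulus) for each row of
// a grid of learning parameters, at fixed beta/alpha, averaged over n_sims
// simulated agents per grid point on one fixed schedule.
// [[Rcpp::export]]
NumericVector cpp_grid_accuracy(int model, NumericMatrix grid, double beta,
                                double alpha, IntegerVector sched,
                                int reversal, int n_sims) {
  int G = grid.nrow(), T = sched.size();
  int L = n_learn_params(model);
  NumericVector acc(G);
  std::vector<double> par(L + 2);
  par[L] = beta;
  par[L + 1] = alpha;
  for (int g = 0; g < G; ++g) {
    for (int k = 0; k < L; ++k) par[k] = grid(g, k);
    long hits = 0;
    for (int sim = 0; sim < n_sims; ++sim) {
      RLState s;
      rl_init(s);
      int correct_acq = -1;
      for (int t = 0; t < T; ++t) {
        double pA = rl_p_A(s, beta, alpha);
        int c = (unif_rand() < pA) ? 0 : 1;
        if (t == 0) correct_acq = c;
        int corr = (t + 1 < reversal) ? correct_acq : 1 - correct_acq;
        double O = (c == corr) ? (double)sched[t] : -(double)sched[t];
        if (c == corr) ++hits;
        rl_update(model, s, c, O, &par[0]);
      }
    }
    acc[g] = (double)hits / ((double)n_sims * T);
  }
  return acc;
}

// One-step-ahead prediction: for each posterior draw, evolve the state along
// the subject's *recorded* history and, before each trial is revealed, sample
// a predicted choice from the current choice probability. Returns per-trial
// counts of predicted==recorded matches across draws.
// [[Rcpp::export]]
List cpp_one_step_ahead(int model, NumericMatrix theta,
                        IntegerVector choice, NumericVector outcome) {
  int S = theta.nrow(), T = choice.size();
  int L = n_learn_params(model);
  IntegerVector match_per_trial(T);
  std::vector<double> par(L + 2);
  long total = 0;
  for (int d = 0; d < S; ++d) {
    for (int k = 0; k < L + 2; ++k) par[k] = theta(d, k);
    double beta = par[L], alpha = par[L + 1];
    RLState s;
    rl_init(s);
    for (int t = 0; t < T; ++t) {
      double pA = rl_p_A(s, beta, alpha);
      int pred = (unif_rand() < pA) ? 0 : 1;
      if (pred == choice[t]) {
        ++match_per_trial[t];
        ++total;
      }
      rl_update(model, s, choice[t], outcome[t], &par[0]);
    }
  }
  return List::create(_["match_per_trial"] = match_per_trial,
                      _["n_match"] = (double)total,
                      _["n_total"] = (double)S * T);
}
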