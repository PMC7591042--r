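# shared fixtures and independent oracles, built in code at test time

default_sched <- build_schedule(seed = 1)

# naive trial-by-trial log-likelihood oracle built from the scalar R update
# functions; intentionally independent of the C++ path it checks
r_seq_loglik <- function(data, model_id, params) {
  p <- params
  st <- init_state(model_id)
  total <- 0
  for (i in seq_len(nrow(data$trials))) {
    ch <- data$trials$choice[i]
    oc <- data$trials$outcome[i]
    pA <- choice_prob(st, p[["beta"]], p[["alpha"]])
    pr <- if (ch == "A") pA else 1 - pA
    total <- total + log(max(pr, 1e-12))
    st <- switch(model_id,
      RW = update_rw(st, ch, oc, p[["eta"]]),
      CU = update_cu(st, ch, oc, p[["eta"]]),
      RP = update_rp(st, ch, oc, p[["eta_rew"]], p[["eta_pun"]]),
      EWA_DL = update_ewa(st, ch, oc, p[["phi"]], p[["rho"]]))
  }
  total
}

# hand-built subject: correct stimulus = first_correct until reversal, then
# the other; phases derived from the reversal index
make_toy_subject <- function(choices, outcomes, reversal,
                             first_correct = "A") {
  n <- length(choices)
  other <- if (first_correct == "A") "B" else "A"
  tr <- data.frame(
    trial = seq_len(n), choice = choices, outcome = outcomes,
    correct_stim = ifelse(seq_len(n) >= reversal, other, first_correct),
    phase = ifelse(seq_len(n) >= reversal, "reversal", "acquisition"),
    stringsAsFactors = FALSE)
  prl_subject("toy", "TD", "adults", tr)
}

# random parameter draw inside a model's support (away from the edges)
random_params <- function(model_id) {
  b <- param_bounds(model_id)
  pad <- 0.02 * (b$upper - b$lower)
  stats::setNames(runif(nrow(b), b$lower + pad, b$upper - pad), b$param)
}

reduced_mcmc <- function(seed = 1L, ...) {
  mcmc_config(chains = 2L, iter = 800L, warmup = 800L, seed = seed,
              on_nonconvergence = "warn", ...)
}
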