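# prlearn

Reinforcement-learning modeling of two-choice **probabilistic reversal
learning (PRL)** behavior, for researchers in computational psychiatry
and developmental cognitive science who need a complete, reproducible
PRL analysis cycle: task simulation, trial-level learning models,
hierarchical Bayesian estimation, principled model comparison, absolute
fit checks, and normative (optimal-parameter) simulations.

## The task and models

The task: 80 trials, two stimuli, 80:20 probabilistic feedback, one
contingency reversal at trial 41. The stimulus chosen on trial 1 is
correct for the acquisition phase; feedback is anti-correlated across
stimuli, and each 40-trial phase contains exactly 8 "misleading"
outcomes that a good learner must ignore.

Four models update stimulus values `V_A, V_B` from outcomes
`O ∈ {+1, −1}` and choose through a softmax
`p(A) = 1 / (1 + exp(β(α − (V_A − V_B))))` with value sensitivity
`β ∈ (0,5)` and indifference point `α ∈ (−0.5, 0.5)`:

| model | update | free parameters |
|---|---|---|
| `RW` | `V_c ← V_c + η(O − V_c)` | `η, β, α` |
| `CU` | RW on the chosen value, plus counterfactual `V_nc ← V_nc + η(−O − V_nc)` | `η, β, α` |
| `RP` | RW on the chosen value with `η_rew` after reward, `η_pun` after punishment | `η_rew, η_pun, β, α` |
| `EWA_DL` | `n_c ← n_c ρ + 1`; `V_c ← (V_c φ n_c,prev + O)/n_c` — a dynamic (shrinking) learning rate | `φ, ρ, β, α` |

Per-group hierarchical Bayesian estimation partially pools subjects
through group-level means and SDs (non-centered, logistic support
transforms, adaptive MCMC in C++ with split-R̂/ESS gates); models are
compared with pseudo-BMA weights stabilized by a Bayesian bootstrap
over subjects; absolute fit uses one-step-ahead posterior prediction
against chance. Because no participant-level data are distributed, a
synthetic-cohort generator emulates the six-group (ASD/TD × children/
adolescents/adults) study design, with each age group generated from
the model that best describes it and ground-truth parameters stored for
recovery analysis.

## Worked example

Simulate one agent with a typical child's parameters and score its
behavior:

```r
library(prlearn)
sched <- build_schedule(seed = 1)                 # 80 trials, reversal at 41
ag <- simulate_agent("CU", c(eta = 0.19, beta = 1.2, alpha = 0), sched, seed = 7)
accuracy_by_phase(ag)
perseverative_errors(ag); win_stay(ag); lose_shift(ag)
```

```
accuracy: overall 0.750, acquisition 0.750, reversal 0.750
perseverative errors: 0.150  win-stay: 0.825  lose-shift: 0.545
```

The agent is correct on 75% of trials in both phases, spends 15% of
reversal trials in perseverative runs (two or more consecutive choices
of the pre-reversal stimulus), repeats its choice after 82.5% of
rewards and switches after 54.5% of punishments — the moderately noisy,
feedback-driven profile expected at `β = 1.2`.

Fit a group hierarchically and recover its mean learning rate:

```r
spec <- group_spec("TD", "children", "CU",
                   means = c(eta = 0.193, beta = 1.202, alpha = -0.042),
                   sds   = c(eta = 0.087, beta = 0.892, alpha = 0.153),
                   n_subjects = 30)
cohort <- generate_cohort(list(spec), sched, seed = 42)
fit <- fit_group(cohort$subjects, "CU",
                 mcmc_config(chains = 2, iter = 1000, warmup = 1000, seed = 7,
                             on_nonconvergence = "warn"))
group_posterior_summary(fit)
```

```
PRL posterior draws: model CU, group TD children, 30 subjects, 2000 draws
max split-R-hat 1.100, min ESS 36
  param   mean     sd  lower   upper
1   eta  0.206 0.0194  0.171  0.2457
2  beta  1.301 0.0659  1.183  1.4382
3 alpha -0.101 0.0427 -0.182 -0.0136
```

The cohort's realized mean learning rate was 0.203; the posterior mean
0.206 with 95% interval [0.171, 0.246] covers it. (At these reduced
desk-scale MCMC settings the sampler warns that one group-level scale
parameter sits at the split-R̂ = 1.1 gate; the defaults — 4 chains ×
1,000 draws — are more conservative.)

End-to-end pipeline with files and manifests:

```r
cfg <- prl_config(seed = 1)      # six groups, three candidate models
run_simulate(cfg, "out")         # schedule.csv, cohort.csv, ground_truth.csv
run_analyze(cfg, "out/cohort.csv", "out")  # metrics, fits, weights, predictions, grids
```

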