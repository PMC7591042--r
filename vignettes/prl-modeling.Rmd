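---
title: "Reinforcement-learning models of probabilistic reversal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reinforcement-learning models of probabilistic reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlearn)
```

## The task and its feedback structure

`prlearn` models two-choice probabilistic reversal learning (PRL). The
default task has 80 trials. The stimulus a participant (or simulated
agent) chooses on trial 1 is defined as *correct* for the acquisition
phase (trials 1–40); from trial 41 the other stimulus becomes the
usually-rewarded one. Feedback is probabilistic at an 80:20 ratio:
within each 40-trial phase exactly 32 trials carry a scheduled reward
(+1) for the currently-correct stimulus and 8 a scheduled punishment
(−1). The two stimuli are anti-correlated: the incorrect choice receives
the negation of the scheduled outcome. The 8 "misleading" punishments
per phase are what makes the task hard — a good learner must ignore
them while still detecting the one true reversal.

The schedule generator (`build_schedule()`) enforces the reward count
per phase exactly and places punishments uniformly at random subject to
a run-length cap of two consecutive punishments. The cap is a design
choice: three or more consecutive misleading punishments are
indistinguishable from an actual reversal over that window, and allowing
them would make task difficulty depend heavily on the schedule draw. The
original task instrument used one fixed pseudorandom sequence whose
exact layout is not public, so only its statistics (counts per phase,
contingency, reversal point) are reproduced here; every result that
depends on the specific placement of misleading feedback should be read
with that in mind.

Outcomes are coded $O \in \{+1, -1\}$. Symmetric coding keeps the
counterfactual update well-formed ($-O$ is again a valid outcome) and
gives the reward–punishment model a clean sign to branch on.

## The learning models

All four models maintain stimulus values $V_A, V_B$, updated after each
outcome, and choose through a softmax. Values start at 0 (an unbiased
start; the task instrument gives no reason to prefer either stimulus).

**Rescorla–Wagner (RW).** $V_c \leftarrow V_c + \eta\,(O - V_c)$ for the
chosen stimulus only. The baseline the three substantive models extend.

**Counterfactual update (CU).** Both stimuli are updated, the unchosen
one with the negated outcome:
$V_c \leftarrow V_c + \eta\,(O - V_c)$,
$V_{nc} \leftarrow V_{nc} + \eta\,(-O - V_{nc})$.
This exploits the anti-correlation of the stimuli and doubles the
effective value separation.

**Reward–punishment (R-P).** Only the chosen value is updated, with
$\eta^{rew}$ after rewards and $\eta^{pun}$ after punishments, capturing
differential sensitivity to feedback valence.

**EWA with dynamic learning rate (EWA-DL).** Each stimulus carries an
experience weight $n$, with
$n_c \leftarrow n_c\,\rho + 1$ and
$V_c \leftarrow (V_c\,\varphi\,n_{c,\text{prev}} + O)/n_c$.
The payoff-decay $\varphi$ acts as an inverse learning rate; the
experience decay $\rho$ makes the effective learning rate shrink as
experience accrues ($n$ saturates at $1/(1-\rho)$), producing
perseveration late in the task. Experience weights start at $n = 1$,
which keeps the first update bounded for every $\rho$
($V_1 = O/(\rho + 1)$); the weight of the *unchosen* stimulus is frozen,
mirroring an update rule that indexes $n$ by the chosen stimulus only.

**Choice rule.** $p(A) = 1/(1 + e^{\beta(\alpha - (V_A - V_B))})$,
with value sensitivity $\beta \in (0, 5)$ and indifference point
$\alpha \in (-0.5, 0.5)$: the value difference at which both options are
equally likely. The $\beta$ upper bound is part of the prior support (it
is enforced by the scale of the support transform, not by clipping).

## Synthetic cohorts

No participant-level data ship with the package; `generate_cohort()`
produces synthetic cohorts emulating a six-group design — two diagnostic
groups (ASD, TD) crossed with three age groups — in which children are
generated from the CU model, adolescents from R-P, and adults from
EWA-DL, the model that best describes each age group. The default group
means, SDs (`default_group_specs()`) and group sizes (81/64/114/90/126/97)
follow the fitted estimates for each cell. Per-subject parameters are
drawn from normals truncated to each parameter's support — means and SDs
are the only distributional information available, and truncation is the
minimal way to respect bounds. Parameter draws and task/choice noise use
separate RNG streams fanned out from the master seed so tests can vary
one noise source while holding the other fixed.

What the generator does *not* emulate: attention lapses, response
biases tied to screen position, within-session drift, IQ or symptom
covariates, or any model-misspecification — every synthetic subject
truly follows its generating model. Passing recovery tests on these
cohorts therefore demonstrates that the estimation machinery works when
the model is correct; it cannot certify behavior on real data, where all
models are approximations.

`recovery_set()` draws parameters uniformly over each parameter's
support (40 subjects per generating model by default). Uniform draws are
an assumption — the original recovery analysis does not state its
generating distribution — chosen to exercise the full parameter range
rather than only the fitted region.

## Behavioral metrics

Accuracy is the proportion of choices of the currently-correct
stimulus, per phase and overall. Perseverative errors are reversal-phase
choices of the pre-reversal correct stimulus belonging to runs of two or
more consecutive such errors, as a proportion of reversal trials. Two
readings of "despite negative feedback" are implemented: the default
counts error trials irrespective of the feedback actually received
(misleading rewards included), reading the phrase as describing the
reversal context; `require_negative_feedback = TRUE` restricts runs to
negatively-reinforced errors. Win-stay (lose-shift) is the proportion of
rewarded (punished) trials whose successor repeats (changes) the choice;
final-trial outcomes have no successor and are excluded, and an empty
denominator yields `NA` rather than 0. The learning criterion — not
fully specified in the source material — is operationalized as a
one-sided exact binomial test of phase accuracy against 0.5 at the 5%
level.

## Hierarchical estimation

`fit_group()` fits one model to one group. Per-subject parameters are
partially pooled: on an unconstrained scale, subject $i$'s raw parameter
$k$ is $\mu_k + \sigma_k z_{ik}$ with $z_{ik} \sim N(0,1)$
(non-centered parameterization), mapped to its support by a logistic
transform — $\text{inv-logit}$ for rates and decays,
$5\,\text{inv-logit}$ for $\beta$, $\text{inv-logit} - 0.5$ for
$\alpha$. Priors are $\mu_k \sim N(0,1)$ and
$\sigma_k \sim \text{half-}N(0, 0.2)$, following the conventions of the
hierarchical-Bayesian toolkits common in this literature. The logistic
(rather than probit-style) transform is a deliberate choice and is the
one place where two reasonable reconstructions of the original analysis
diverge; the difference is a reparameterization of the same support.

Sampling is adaptive random-walk Metropolis-within-Gibbs, written in
C++: scalar updates of every $z_{ik}$, $\mu_k$ and $\log\sigma_k$ per
sweep, with per-coordinate step sizes tuned toward 0.44 acceptance
during warmup only (so the post-warmup kernel is fixed and valid).
Defaults retain 4,000 draws (4 chains × 1,000) after 1,000 warmup
sweeps. Convergence is gated on split-$\widehat{R} \le 1.1$ computed for
every group-level and subject-level parameter, together with an
autocorrelation-based effective sample size; a violation raises an error
carrying the offending parameter names (or a warning, per
configuration). Each trial's choice probability is floored at $10^{-12}$
in the likelihood to keep pathological proposals finite.

Random-walk sampling mixes more slowly than gradient-based samplers;
the group-level scale parameters are the slowest coordinates. The
diagnostics are computed on every parameter precisely so that
insufficient chains surface as a loud failure rather than a quietly
biased estimate. For desk-scale work (tests, examples) 2 chains ×
800–1,000 retained draws after equal warmup proved adequate for the
focal learning parameters; the defaults are deliberately larger.

Two group-level summaries are exposed: the *cohort mean* (per draw, the
average of the fitted subjects' transformed parameters) and the
*location* (the transformed group mean $\mu$). The cohort mean is the
quantity directly comparable to the realized average of a synthetic
cohort's true parameters, and it is what the parameter-recovery tests
check. A caution from those tests: with 80 trials, the indifference
point $\alpha$ is only weakly identified and its estimates can be
systematically displaced from the generating values (the per-subject
maximum-likelihood oracle shows the same displacement, so it is a
property of the data, not the sampler); the learning parameters and
$\beta$ recover well.

## Model comparison

`model_weights()` implements pseudo-BMA weights with Bayesian-bootstrap
stabilization over subjects (subjects, not trials, are the exchangeable
units). For each model the per-subject expected log predictive density
is the log posterior-mean likelihood minus an effective-parameter
penalty — the gap between the log of the mean likelihood and the mean
log-likelihood over draws. Dirichlet(1) subject weights are drawn 10,000
times; within each replicate the weighted elpd sums are
softmax-normalized across models, and replicates are averaged. The
result is invariant to adding a constant to every matrix, sums to one,
and concentrates on a model that dominates by a few nats per subject.
Ties in the winning model break toward the model with fewer parameters.
A leave-one-out-style elpd estimator was considered as an alternative;
the penalized in-sample estimator was kept because it matches the
effective-number-of-parameters accounting used in the source analyses.

## One-step-ahead prediction

`one_step_ahead()` measures absolute fit: for each posterior draw the
model state is evolved along the subject's *recorded* history, and
before each trial is revealed a choice is sampled from the current
softmax. Accuracy is matches over draws × trials, tested against 50%
with an exact binomial test. Because the state always conditions on the
subject's actual past, this cannot drift the way free simulation does;
an accuracy near 0.5 under a fitted model is a diagnosis of a
random-responder, not a failed simulation.

## Optimal learning parameters

`optimal_learning_params()` asks which learning-parameter values a
*well-calibrated* agent should have on this task: for each grid point it
simulates agents at fixed $\beta$ and $\alpha = 0$ and scores mean
accuracy against the currently-correct stimulus, reversal included. The
$\beta$ anchors default to the fitted group-level means of the age group
each model wins — CU 1.2 (children), R-P 2.5 (adolescents), EWA-DL 1.3
(adults) — because the optimum is strongly $\beta$-dependent and those
are the only printed anchors available; the anchor is an explicit
argument. Grids default to 101 points for the 1-D (CU/RW) case and
51 × 51 for the 2-D (R-P, EWA-DL) cases, with 2,000 and 1,000 simulated
agents per point; argmax ties break toward smaller parameter values.

Two properties of these surfaces deserve emphasis. First, they are
*plateaus*: near the optimum, accuracy differences between quite
different parameter values are of order 0.001–0.01, so the argmax has
substantial Monte-Carlo jitter even at thousands of simulations per
point, and its location shifts with the feedback schedule realization,
the $\beta$ anchor, and the task horizon. Second, the qualitative
structure is robust: the R-P optimum always has
$\eta^{rew} > \eta^{pun}$, the CU optimum is a moderate learning rate
well below 0.5, and the EWA-DL optimum has high $\varphi$ with
$\rho$ near 0. Quantitative argmax coordinates should be quoted with
their grid step and simulation count, and compared across studies only
with matched simulation designs.

## Pipeline

`prl_config()` collects every setting (task, group specs, candidate
models, MCMC, comparison, prediction, grids, master seed) and
round-trips through JSON. `run_simulate()` writes the schedule, the
trial-level cohort CSV and its ground-truth sidecar; `run_analyze()`
runs metrics → per-group fits of all candidate models → model weights →
one-step-ahead prediction under each group's winning model → optimality
grids, writing one CSV per stage plus a manifest carrying the config
hash, the master seed and any per-stage failures (downstream stages for
an affected group are skipped, not silently absorbed). The master seed
is fanned out deterministically to per-stage streams, so a rerun with
the same configuration reproduces every file byte-for-byte.

## Numerical choices, scales and limitations

- Likelihood floor $10^{-12}$ per trial; softmax computed in the
  overflow-safe branch form.
- Truncated-normal draws by inverse-CDF; a spec whose truncated mass is
  essentially zero raises an error rather than looping.
- Desk-scale defaults used throughout the test suite: cohorts of 25–50
  subjects per group, 2 chains × 800 retained draws, 20 replications
  for coverage, 40 subjects per model for recovery, and the grid sizes
  above. These sizes were chosen so the full analysis cycle runs on a
  single CPU in minutes while keeping Monte-Carlo error comfortably
  below the effect sizes being tested.
- The sampler is random-walk based: for models or datasets far outside
  the PRL design here (many more parameters, strong posterior
  correlations), a gradient-based sampler would be preferable.
- All results on synthetic cohorts inherit the generator's assumptions;
  see the synthetic-cohorts section for what that does and does not
  license.
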