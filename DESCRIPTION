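Package: prlearn
Title: Reinforcement-Learning Models of Probabilistic Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian modeling of two-choice
    probabilistic reversal learning (PRL) behavior. Provides the 80-trial
    midway-reversal task environment with 80:20 probabilistic feedback;
    four trial-level learning models (Rescorla-Wagner, counterfactual
    update, reward-punishment with separate learning rates, and
    experience-weighted attraction with a dynamic learning rate) under a
    softmax choice rule with an indifference point; synthetic-cohort
    generation emulating a six-group diagnosis-by-age design; behavioral
    metrics (phase accuracy, perseverative errors, win-stay, lose-shift,
    learning criterion); per-group hierarchical MCMC estimation with
    convergence diagnostics; pseudo-BMA model weights with Bayesian-
    bootstrap stabilization and a model-recovery harness; one-step-ahead
    posterior prediction; and grid simulations locating the learning
    parameters that maximize task accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
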