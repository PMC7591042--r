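#' Initial latent state of a learning model
#'
#' All models start with both stimulus values at 0 (an unbiased start); the
#' EWA-DL model additionally carries experience weights, initialized at 1 so
#' that the first update is well-defined for every decay value.
#'
#' @param model_id One of [prl_models()].
#' @return A list with `V` (named numeric, values of A and B) and, for
#'   `"EWA_DL"`, `n` (named numeric experience weights).
#' @export
init_state <- function(model_id) {
  model_id <- match.arg(model_id, prl_models())
  st <- list(V = c(A = 0, B = 0))
  if (model_id == "EWA_DL") st$n <- c(A = 1, B = 1)
  st
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single value in [0, 1]", name), call. = FALSE)
  }
  x
}

check_outcome <- function(outcome) {
  if (!is.numeric(outcome) || length(outcome) != 1L ||
      !(outcome %in% c(-1, 1))) {
    stop("outcome must be +1 or -1", call. = FALSE)
  }
  outcome
}

#' Rescorla-Wagner update (chosen stimulus only)
#'
#' `V_c <- V_c + eta * (O - V_c)`; the unchosen stimulus is untouched.
#'
#' @param state A state from [init_state()].
#' @param choice `"A"` or `"B"`.
#' @param outcome `+1` or `-1`.
#' @param eta Learning rate in `[0, 1]`.
#' @return The updated state.
#' @export
update_rw <- function(state, choice, outcome, eta) {
  check_stim(choice, "choice"); check_outcome(outcome)
  check_rate(eta, "eta")
  state$V[choice] <- state$V[choice] + eta * (outcome - state$V[choice])
  state
}

#' Counterfactual update (both stimuli)
#'
#' The chosen stimulus is updated with the actual prediction error and the
#' unchosen stimulus with the counterfactual one, exploiting the
#' anti-correlation of the two stimuli:
#' `V_c <- V_c + eta * (O - V_c)`, `V_nc <- V_nc + eta * (-O - V_nc)`.
#'
#' @inheritParams update_rw
#' @return The updated state.
#' @export
update_cu <- function(state, choice, outcome, eta) {
  check_stim(choice, "choice"); check_outcome(outcome)
  check_rate(eta, "eta")
  nc <- if (choice == "A") "B" else "A"
  state$V[choice] <- state$V[choice] + eta * (outcome - state$V[choice])
  state$V[nc] <- state$V[nc] + eta * (-outcome - state$V[nc])
  state
}

#' Reward-punishment update (separate learning rates)
#'
#' Only the chosen stimulus is updated; the learning rate is `eta_rew` after
#' a reward (`O > 0`) and `eta_pun` after a punishment (`O < 0`).
#'
#' @inheritParams update_rw
#' @param eta_rew,eta_pun Learning rates in `[0, 1]`.
#' @return The updated state.
#' @export
update_rp <- function(state, choice, outcome, eta_rew, eta_pun) {
  check_stim(choice, "choice"); check_outcome(outcome)
  check_rate(eta_rew, "eta_rew"); check_rate(eta_pun, "eta_pun")
  if (outcome == 0) stop("outcome 0 has no defined branch", call. = FALSE)
  eta <- if (outcome > 0) eta_rew else eta_pun
  state$V[choice] <- state$V[choice] + eta * (outcome - state$V[choice])
  state
}

#' Experience-weighted attraction update with dynamic learning rate
#'
#' The chosen stimulus's experience weight grows as
#' `n_c <- n_c * rho + 1` and its value is updated as
#' `V_c <- (V_c * phi * n_c_prev + O) / n_c`. As experience accrues the
#' effective learning rate `1/n_c` shrinks (for `rho > 0`), producing
#' sluggish updating late in the task. The unchosen stimulus's value and
#' weight are untouched.
#'
#' @inheritParams update_rw
#' @param phi Payoff decay in `[0, 1]` (the inverse of a learning rate:
#'   higher `phi` retains more of the old value).
#' @param rho Experience decay in `[0, 1]`.
#' @return The updated state.
#' @export
update_ewa <- function(state, choice, outcome, phi, rho) {
  check_stim(choice, "choice"); check_outcome(outcome)
  check_rate(phi, "phi"); check_rate(rho, "rho")
  if (is.null(state$n)) stop("state lacks experience weights; use init_state(\"EWA_DL\")",
                             call. = FALSE)
  n_prev <- state$n[choice]
  state$n[choice] <- n_prev * rho + 1
  state$V[choice] <- (state$V[choice] * phi * n_prev + outcome) / state$n[choice]
  state
}

#' Softmax choice probability
#'
#' Probability of choosing stimulus A given the current stimulus values:
#' `p(A) = 1 / (1 + exp(beta * (alpha - (V_A - V_B))))`, with
#' `p(B) = 1 - p(A)`. `beta` is the value sensitivity (inverse temperature)
#' and `alpha` the indifference point: the value difference at which both
#' options are equally likely.
#'
#' @param state A state from [init_state()] (only `V` is used).
#' @param beta Value sensitivity in `(0, 5)`.
#' @param alpha Indifference point in `(-0.5, 0.5)`.
#' @return `p(A)`, numerically stable for extreme arguments.
#' @export
choice_prob <- function(state, beta, alpha = 0) {
  x <- beta * (alpha - (state$V[["A"]] - state$V[["B"]]))
  if (x > 0) {
    e <- exp(-x)
    e / (1 + e)
  } else {
    1 / (1 + exp(x))
  }
}

# apply one model update given a named parameter vector (canonical order)
apply_update <- function(model_id, state, choice, outcome, params) {
  switch(model_id,
    RW = update_rw(state, choice, outcome, params[["eta"]]),
    CU = update_cu(state, choice, outcome, params[["eta"]]),
    RP = update_rp(state, choice, outcome, params[["eta_rew"]],
                   params[["eta_pun"]]),
    EWA_DL = update_ewa(state, choice, outcome, params[["phi"]],
                        params[["rho"]]))
}

#' Log-likelihood of a subject's choice sequence
#'
#' Evaluates the recorded choices under a model and parameter set: starting
#' from the initial state, each trial contributes the log-probability of the
#' recorded choice under the softmax rule, after which the state is updated
#' with the recorded choice and outcome. No re-simulation takes place. Each
#' trial's probability is floored at `1e-12` before taking logs to guard
#' against pathological parameter draws.
#'
#' @param data A [prl_subject()] object (or anything with a `trials`
#'   data.frame holding `choice` and `outcome`).
#' @param model_id One of [prl_models()].
#' @param params Named parameter vector for the model (see
#'   [param_bounds()]).
#' @param per_trial If `TRUE`, return the per-trial log-probability vector
#'   instead of the sum.
#' @return Total log-likelihood, or a per-trial vector.
#' @export
sequence_loglik <- function(data, model_id, params, per_trial = FALSE) {
  model_id <- match.arg(model_id, prl_models())
  p <- canonical_params(model_id, params)
  tr <- data$trials
  ll <- cpp_seq_loglik(model_code(model_id), unname(p),
                       as.integer(tr$choice == "B"),
                       as.numeric(tr$outcome))
  if (per_trial) ll else sum(ll)
}
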