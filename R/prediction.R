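#' One-step-ahead posterior prediction for one subject
#'
#' Absolute-fit check: for each posterior draw of the subject's parameters,
#' the model state is evolved along the subject's *recorded* choices and
#' outcomes, and before each trial is revealed a choice is sampled from the
#' current softmax probability. Predictive accuracy is the number of
#' sampled choices matching the recorded ones divided by draws x trials,
#' with an exact binomial test against chance (50%).
#'
#' @param draws A `prl_draws` object containing the subject, or a plain
#'   draws x parameters matrix on the natural scale (canonical parameter
#'   order).
#' @param data The subject's [prl_subject()] record.
#' @param n_iter Number of draws to use (default: all retained draws; must
#'   not exceed what is available).
#' @param seed RNG seed for the sampled predictions.
#' @param model_id Required only when `draws` is a plain matrix.
#' @return An object of class `prl_prediction`: list with `accuracy`,
#'   `p_value`, `match_freq` (per-trial match frequency over draws),
#'   `n_draws`, `n_trials`.
#' @export
one_step_ahead <- function(draws, data, n_iter = NULL, seed = 1L,
                           model_id = NULL) {
  if (inherits(draws, "prl_draws")) {
    model_id <- draws$model_id
    theta <- subject_draws(draws, data$subject_id)
  } else {
    if (is.null(model_id)) {
      stop("model_id is required when draws is a plain matrix",
           call. = FALSE)
    }
    model_id <- match.arg(model_id, prl_models())
    theta <- as.matrix(draws)
  }
  if (!is.null(n_iter)) {
    if (n_iter > nrow(theta)) {
      stop("n_iter exceeds the number of available draws", call. = FALSE)
    }
    theta <- theta[seq_len(n_iter), , drop = FALSE]
  }
  tr <- data$trials
  set.seed(as.integer(seed))
  res <- cpp_one_step_ahead(model_code(model_id), theta,
                            as.integer(tr$choice == "B"),
                            as.numeric(tr$outcome))
  acc <- res$n_match / res$n_total
  pv <- binom.test(round(res$n_match), round(res$n_total), p = 0.5,
                   alternative = "greater")$p.value
  structure(list(accuracy = acc, p_value = pv,
                 match_freq = res$match_per_trial / nrow(theta),
                 n_draws = nrow(theta), n_trials = nrow(tr)),
            class = "prl_prediction")
}

#' @export
print.prl_prediction <- function(x, ...) {
  cat(sprintf("One-step-ahead prediction: accuracy %.3f over %d draws x %d trials (p = %.3g vs chance)\n",
              x$accuracy, x$n_draws, x$n_trials, x$p_value))
  invisible(x)
}

# default value-sensitivity anchors for the optimality simulations: the
# fitted group-level beta of the age group each model wins (children for
# CU, adolescents for RP, adults for EWA-DL)
default_optimal_beta <- function(model_id) {
  switch(model_id, CU = 1.2, RP = 2.5, EWA_DL = 1.3, RW = 1.2)
}

#' Optimal learning parameters by grid simulation
#'
#' Simulates agents across a grid of learning-parameter values at fixed
#' `beta` and `alpha` and scores each grid point by mean choice accuracy
#' (choice equals the currently-correct stimulus, reversal included). For
#' one-learning-parameter models (`RW`, `CU`) the grid is 1-D over `eta`;
#' for `RP` it is 2-D over `(eta_rew, eta_pun)` and for `EWA_DL` 2-D over
#' `(phi, rho)`. The argmax is reported with ties broken toward smaller
#' parameter values.
#'
#' @param model_id One of [prl_models()].
#' @param schedule A [build_schedule()] object.
#' @param grid_points Grid resolution per axis (default 101 for 1-D
#'   models, 51 for 2-D models, i.e. steps of 0.01 and 0.02 on `[0, 1]`).
#' @param n_sims Simulated agents per grid point (default 2,000 for 1-D,
#'   1,000 for 2-D grids).
#' @param beta Value sensitivity held fixed; defaults to the fitted
#'   group-level mean of the age group whose behavior the model wins
#'   (CU: 1.2, RP: 2.5, EWA_DL: 1.3).
#' @param alpha Indifference point held fixed (default 0).
#' @param seed RNG seed.
#' @return An object of class `prl_grid`: list with `surface` (data.frame
#'   of grid values, mean accuracy, and binomial SE), `argmax` (named
#'   vector), `model_id`, `beta`, `alpha`, `n_sims`, `seed`.
#' @export
optimal_learning_params <- function(model_id, schedule,
                                    grid_points = NULL, n_sims = NULL,
                                    beta = NULL, alpha = 0, seed = 1L) {
  model_id <- match.arg(model_id, prl_models())
  stopifnot(inherits(schedule, "prl_schedule"))
  b <- param_bounds(model_id)
  learn <- b$param[!(b$param %in% c("beta", "alpha"))]
  two_d <- length(learn) == 2L
  if (is.null(grid_points)) grid_points <- if (two_d) 51L else 101L
  if (grid_points < 1L) stop("grid must be nonempty", call. = FALSE)
  if (is.null(n_sims)) n_sims <- if (two_d) 1000L else 2000L
  if (is.null(beta)) beta <- default_optimal_beta(model_id)

  axis <- seq(0, 1, length.out = grid_points)
  grid <- if (two_d) {
    as.matrix(expand.grid(axis, axis))   # varies first axis fastest
  } else {
    matrix(axis, ncol = 1)
  }
  colnames(grid) <- learn

  set.seed(as.integer(seed))
  acc <- cpp_grid_accuracy(model_code(model_id), grid, beta, alpha,
                           schedule$scheduled_outcome,
                           schedule$reversal_trial, as.integer(n_sims))
  se <- sqrt(acc * (1 - acc) / (n_sims * schedule$n_trials))
  surface <- data.frame(grid, accuracy = acc, se = se)
  # ties toward smaller values: order grid rows ascending, take first max
  ord <- do.call(order, as.data.frame(grid[, rev(seq_along(learn)),
                                           drop = FALSE]))
  best <- ord[which.max(acc[ord])]
  argmax <- stats::setNames(as.numeric(grid[best, ]), learn)
  structure(list(surface = surface, argmax = argmax,
                 accuracy_max = acc[best], model_id = model_id,
                 beta = beta, alpha = alpha, n_sims = as.integer(n_sims),
                 seed = as.integer(seed)),
            class = "prl_grid")
}

#' @export
print.prl_grid <- function(x, ...) {
  cat(sprintf("Optimal-parameter grid (%s, beta = %.2f, alpha = %.2f, %d sims/point):\n",
              x$model_id, x$beta, x$alpha, x$n_sims))
  cat("  argmax:", paste(sprintf("%s = %.3f", names(x$argmax), x$argmax),
                         collapse = ", "),
      sprintf(" (accuracy %.3f)\n", x$accuracy_max))
  invisible(x)
}
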