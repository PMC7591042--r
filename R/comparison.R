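log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Pseudo-BMA model weights with Bayesian-bootstrap stabilization
#'
#' For each model, the expected log pointwise predictive density (elpd) per
#' subject is estimated from its pointwise log-likelihood matrix as the log
#' posterior-mean likelihood minus an effective-number-of-parameters
#' penalty (the gap between the log of the mean likelihood and the mean
#' log-likelihood over draws). Weights are then stabilized by a Bayesian
#' bootstrap over subjects: Dirichlet(1, ..., 1) subject weights are drawn
#' `n_bootstrap` times, the weighted elpd sums are softmax-normalized
#' across models within each replicate, and replicates are averaged. The
#' result is a simplex: nonnegative weights summing to 1.
#'
#' @param loglik_list Named list (one element per model) of draws x
#'   subjects log-likelihood matrices sharing the subject dimension, as
#'   from [pointwise_loglik()].
#' @param n_bootstrap Number of Bayesian-bootstrap replicates (default
#'   10,000).
#' @param seed RNG seed.
#' @return An object of class `prl_weights`: a data.frame with one row per
#'   model (`model`, `weight`, `elpd`, `penalty`) and attributes
#'   `n_bootstrap` and `seed`.
#' @export
model_weights <- function(loglik_list, n_bootstrap = 10000L, seed = 1L) {
  if (is.null(names(loglik_list)) || any(names(loglik_list) == "")) {
    stop("loglik_list must be a named list (one entry per model)",
         call. = FALSE)
  }
  M <- length(loglik_list)
  ns <- vapply(loglik_list, ncol, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all log-likelihood matrices must share the subject dimension",
         call. = FALSE)
  }
  N <- ns[[1]]
  # per-subject elpd with complexity penalty, per model
  elpd <- matrix(NA_real_, nrow = M, ncol = N,
                 dimnames = list(names(loglik_list), NULL))
  pen <- numeric(M)
  for (m in seq_len(M)) {
    ll <- loglik_list[[m]]
    S <- nrow(ll)
    lppd <- apply(ll, 2, log_sum_exp) - log(S)
    p_eff <- lppd - colMeans(ll)
    elpd[m, ] <- lppd - p_eff
    pen[m] <- sum(p_eff)
  }
  if (M == 1L) {
    warning("only one model supplied; returning weight 1", call. = FALSE)
    wts <- 1
  } else {
    set.seed(as.integer(seed))
    acc <- numeric(M)
    for (b in seq_len(n_bootstrap)) {
      w <- rgamma(N, 1)
      w <- w / sum(w)
      z <- N * as.numeric(elpd %*% w)
      z <- z - max(z)
      e <- exp(z)
      acc <- acc + e / sum(e)
    }
    wts <- acc / n_bootstrap
  }
  out <- data.frame(model = names(loglik_list), weight = wts,
                    elpd = rowSums(elpd), penalty = pen,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("prl_weights", "data.frame"),
            n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed))
}

# winner with ties broken toward the simpler model (fewer parameters)
winning_model <- function(weights) {
  k <- vapply(weights$model, function(m) nrow(param_bounds(m)), integer(1))
  ord <- order(-weights$weight, k)
  weights$model[ord[1]]
}

#' Model-recovery confusion analysis
#'
#' For each generating model, simulates a recovery cohort
#' ([recovery_set()]), fits every candidate model hierarchically, computes
#' pseudo-BMA weights, and records which model wins. Identifiable models
#' produce a weight matrix whose diagonal entries are the row maxima. Fit
#' failures are recorded per cell rather than aborting the analysis.
#'
#' @param n_per_model Synthetic participants per generating model
#'   (default 40).
#' @param schedule A [build_schedule()] object.
#' @param fit_config An [mcmc_config()] for the candidate fits.
#' @param seed Master seed.
#' @param models Candidate (and generating) models.
#' @param n_bootstrap Bootstrap replicates for [model_weights()].
#' @return A list with `weights` (generator x candidate weight matrix),
#'   `winner` (named character, winner per generator), and `errors`
#'   (messages for failed cells, if any).
#' @export
recover_models <- function(n_per_model = 40L, schedule,
                           fit_config = mcmc_config(),
                           seed = 1L,
                           models = c("CU", "RP", "EWA_DL"),
                           n_bootstrap = 10000L) {
  W <- matrix(NA_real_, nrow = length(models), ncol = length(models),
              dimnames = list(generator = models, candidate = models))
  winner <- stats::setNames(rep(NA_character_, length(models)), models)
  errors <- list()
  if (n_per_model == 0L) {
    return(list(weights = W[0, , drop = FALSE], winner = winner[0],
                errors = errors))
  }
  for (gi in seq_along(models)) {
    gen <- models[gi]
    cohort <- recovery_set(gen, n_per_model, schedule,
                           seed = derive_seed(seed, gi))
    lls <- list()
    for (cand in models) {
      fit <- tryCatch(
        fit_group(cohort$subjects, cand,
                  modifyList(fit_config,
                             list(seed = derive_seed(seed, 100L + gi)))),
        error = function(e) e)
      if (inherits(fit, "error")) {
        errors[[paste(gen, cand, sep = "->")]] <- conditionMessage(fit)
        next
      }
      lls[[cand]] <- pointwise_loglik(fit, cohort$subjects)
    }
    if (length(lls) >= 2) {
      wt <- model_weights(lls, n_bootstrap = n_bootstrap,
                          seed = derive_seed(seed, 200L + gi))
      W[gen, wt$model] <- wt$weight
      winner[gen] <- winning_model(wt)
    }
  }
  list(weights = W, winner = winner, errors = errors)
}
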