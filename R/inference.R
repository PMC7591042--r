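#' MCMC configuration
#'
#' Settings for [fit_group()]. Defaults retain 4,000 draws (4 chains x
#' 1,000 kept iterations) after 1,000 warmup sweeps per chain, with a
#' half-Normal(0, 0.2) prior SD on the group-level scale parameters and a
#' split-R-hat convergence gate at 1.1.
#'
#' @param chains Number of chains.
#' @param iter Retained iterations per chain.
#' @param warmup Warmup (adaptation) sweeps per chain, discarded.
#' @param seed RNG seed for the sampler.
#' @param sigma_prior_sd Scale of the half-Normal prior on group SDs.
#' @param rhat_max Convergence threshold on split-R-hat.
#' @param on_nonconvergence `"error"` (default) or `"warn"` when any
#'   parameter exceeds `rhat_max`.
#' @return A list of class `prl_mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, iter = 1000L, warmup = 1000L,
                        seed = 1L, sigma_prior_sd = 0.2, rhat_max = 1.1,
                        on_nonconvergence = c("error", "warn")) {
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 sigma_prior_sd = sigma_prior_sd, rhat_max = rhat_max,
                 on_nonconvergence = match.arg(on_nonconvergence)),
            class = "prl_mcmc_config")
}

#' Split-R-hat of one parameter
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends register as apparent non-convergence.
#'
#' @param x An iterations x chains matrix of draws.
#' @return The split-R-hat statistic.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (W < 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size of one parameter
#'
#' Autocorrelation-based multi-chain effective sample size using Geyer's
#' initial positive sequence to truncate the autocorrelation sum.
#'
#' @param x An iterations x chains matrix of draws.
#' @return Estimated effective number of draws.
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  chain_means <- colMeans(x)
  chain_vars <- apply(x, 2, var)
  W <- mean(chain_vars)
  var_plus <- (n - 1) / n * W + (if (m > 1) var(chain_means) else 0)
  if (var_plus < 1e-300) return(n * m)
  max_lag <- min(n - 1, 200)
  # average within-chain autocovariance per lag
  acov <- sapply(seq_len(ncol(x)), function(j) {
    a <- acf(x[, j], lag.max = max_lag, plot = FALSE, type = "covariance",
             demean = TRUE)
    as.numeric(a$acf)
  })
  acov <- rowMeans(matrix(acov, nrow = max_lag + 1))
  rho <- 1 - (W - acov) / var_plus
  # Geyer initial positive sequence over lag pairs
  s <- 0
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t + 1] + rho[t + 2]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- n * m / (1 + 2 * s)
  min(ess, n * m)
}

new_convergence_error <- function(msg, bad) {
  structure(class = c("prl_convergence_error", "error", "condition"),
            list(message = msg, call = NULL, parameters = bad))
}

#' Fit one model to one group hierarchically
#'
#' Hierarchical Bayesian estimation by MCMC of one learning model for a set
#' of subjects sharing a group label. Per-subject parameters are partially
#' pooled through group-level means and SDs on an unconstrained scale
#' (non-centered parameterization) and mapped to their supports by scaled
#' inverse-logit transforms; priors are Normal(0,1) on group means and
#' half-Normal on group SDs. Sampling is adaptive random-walk
#' Metropolis-within-Gibbs (see [mcmc_config()]); convergence is gated on
#' split-R-hat, and a failure raises (or warns, per config) a diagnostic
#' condition naming the offending parameters.
#'
#' @param subjects A list of [prl_subject()] objects or a `prl_cohort`; at
#'   least two subjects sharing one diagnosis and age group, all with the
#'   same number of trials.
#' @param model_id One of [prl_models()].
#' @param config An [mcmc_config()].
#' @return An object of class `prl_draws` with elements `theta`
#'   (iterations x chains x subjects x parameters array of transformed
#'   per-subject draws), `mu` and `sigma` (group-level draws on the raw
#'   scale), `param_names`, `subject_ids`, `group`, `diagnostics` (one row
#'   per monitored parameter with split-R-hat and effective sample size)
#'   and `config`.
#' @export
fit_group <- function(subjects, model_id, config = mcmc_config()) {
  if (inherits(subjects, "prl_cohort")) subjects <- subjects$subjects
  model_id <- match.arg(model_id, prl_models())
  if (length(subjects) < 2L) {
    stop("fit_group needs at least 2 subjects", call. = FALSE)
  }
  labels <- unique(vapply(subjects, function(s) {
    paste(s$diagnosis, s$age_group)
  }, character(1)))
  if (length(labels) != 1L) {
    stop("all subjects must share one group label; found: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  nt <- unique(vapply(subjects, function(s) nrow(s$trials), integer(1)))
  if (length(nt) != 1L) {
    stop("all subjects must have the same number of trials", call. = FALSE)
  }
  choices <- t(vapply(subjects, function(s) {
    as.integer(s$trials$choice == "B")
  }, integer(nt)))
  outcomes <- t(vapply(subjects, function(s) {
    as.numeric(s$trials$outcome)
  }, numeric(nt)))

  set.seed(config$seed)
  fit <- cpp_fit_group(model_code(model_id), choices, outcomes,
                       config$warmup, config$iter, config$chains,
                       config$sigma_prior_sd)
  pn <- param_bounds(model_id)$param
  K <- length(pn)
  N <- length(subjects)
  dimnames(fit$mu) <- list(NULL, NULL, pn)
  dimnames(fit$sigma) <- list(NULL, NULL, pn)
  subject_ids <- vapply(subjects, function(s) s$subject_id, character(1))
  dimnames(fit$theta) <- list(NULL, NULL, subject_ids, pn)

  diag_rows <- list()
  for (k in seq_len(K)) {
    for (what in c("mu", "sigma")) {
      m <- fit[[what]][, , k, drop = FALSE]
      dim(m) <- c(config$iter, config$chains)
      diag_rows[[length(diag_rows) + 1L]] <-
        data.frame(parameter = sprintf("%s[%s]", what, pn[k]),
                   rhat = split_rhat(m), ess = ess_basic(m),
                   stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(N)) {
    for (k in seq_len(K)) {
      m <- fit$theta[, , i, k, drop = FALSE]
      dim(m) <- c(config$iter, config$chains)
      diag_rows[[length(diag_rows) + 1L]] <-
        data.frame(parameter = sprintf("theta[%s,%s]", subject_ids[i], pn[k]),
                   rhat = split_rhat(m), ess = ess_basic(m),
                   stringsAsFactors = FALSE)
    }
  }
  diagnostics <- do.call(rbind, diag_rows)

  out <- structure(list(model_id = model_id,
                        group = list(diagnosis = subjects[[1]]$diagnosis,
                                     age_group = subjects[[1]]$age_group),
                        param_names = pn, subject_ids = subject_ids,
                        mu = fit$mu, sigma = fit$sigma, theta = fit$theta,
                        diagnostics = diagnostics, config = config),
                   class = "prl_draws")

  bad <- diagnostics$parameter[diagnostics$rhat > config$rhat_max]
  if (length(bad) > 0) {
    msg <- sprintf("MCMC did not converge (split-R-hat > %.2f) for: %s",
                   config$rhat_max,
                   paste(utils::head(bad, 10), collapse = ", "))
    if (config$on_nonconvergence == "error") {
      stop(new_convergence_error(msg, bad))
    }
    warning(msg, call. = FALSE)
  }
  out
}

#' @export
print.prl_draws <- function(x, ...) {
  cat(sprintf("PRL posterior draws: model %s, group %s %s, %d subjects, %d draws\n",
              x$model_id, x$group$diagnosis, x$group$age_group,
              length(x$subject_ids),
              dim(x$theta)[1] * dim(x$theta)[2]))
  cat(sprintf("max split-R-hat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' Flattened per-subject posterior draws
#'
#' @param draws A `prl_draws` object.
#' @param subject_id One of `draws$subject_ids`.
#' @return A (total draws) x (parameters) matrix on the natural scale.
#' @export
subject_draws <- function(draws, subject_id) {
  i <- match(subject_id, draws$subject_ids)
  if (is.na(i)) stop("subject not present in draws: ", subject_id,
                     call. = FALSE)
  th <- draws$theta[, , i, , drop = FALSE]
  S <- dim(th)[1] * dim(th)[2]
  m <- matrix(th, nrow = S)
  colnames(m) <- draws$param_names
  m
}

#' Group-level posterior draws on the parameter scale
#'
#' Two summaries of the group: `"cohort_mean"` (per draw, the mean of the
#' fitted subjects' transformed parameters — the posterior of this
#' cohort's average parameter) and `"location"` (the group-level location
#' `mu` mapped through the support transform — the population-typical
#' parameter).
#'
#' @param draws A `prl_draws` object.
#' @param type `"cohort_mean"` or `"location"`.
#' @return A (total draws) x (parameters) matrix.
#' @export
group_parameter_draws <- function(draws, type = c("cohort_mean", "location")) {
  type <- match.arg(type)
  K <- length(draws$param_names)
  S <- dim(draws$theta)[1] * dim(draws$theta)[2]
  if (type == "cohort_mean") {
    m <- sapply(seq_len(K), function(k) {
      th <- draws$theta[, , , k, drop = FALSE]
      rowMeans(matrix(th, nrow = S))
    })
  } else {
    b <- param_bounds(draws$model_id)
    m <- sapply(seq_len(K), function(k) {
      raw <- as.numeric(draws$mu[, , k])
      il <- 1 / (1 + exp(-raw))
      if (b$param[k] == "beta") 5 * il
      else if (b$param[k] == "alpha") il - 0.5
      else il
    })
  }
  m <- matrix(m, nrow = S)
  colnames(m) <- draws$param_names
  m
}

#' Posterior summary of group-level parameters
#'
#' @param draws A `prl_draws` object.
#' @param type See [group_parameter_draws()].
#' @param prob Central credible-interval mass (default 0.95).
#' @return A data.frame with columns `param`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
group_posterior_summary <- function(draws, type = "cohort_mean",
                                    prob = 0.95) {
  m <- group_parameter_draws(draws, type)
  a <- (1 - prob) / 2
  data.frame(param = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, sd),
             lower = apply(m, 2, quantile, probs = a),
             upper = apply(m, 2, quantile, probs = 1 - a),
             row.names = NULL, stringsAsFactors = FALSE)
}

# support transform used for unconstrained optimization / sampling
transform_raw <- function(raw, param_names) {
  il <- 1 / (1 + exp(-raw))
  out <- il
  out[param_names == "beta"] <- 5 * il[param_names == "beta"]
  out[param_names == "alpha"] <- il[param_names == "alpha"] - 0.5
  stats::setNames(out, param_names)
}

#' Per-subject maximum-likelihood fit
#'
#' Bounded maximum-likelihood estimation of one subject's parameters by
#' quasi-Newton optimization on the unconstrained (logit) scale with random
#' restarts. Mainly a fast independent check on the hierarchical fits.
#'
#' @param data A [prl_subject()] object.
#' @param model_id One of [prl_models()].
#' @param n_restarts Number of random initializations (best kept).
#' @param seed RNG seed for the initializations.
#' @return A list with `params` (named, natural scale), `loglik`, and
#'   `convergence` (optim code of the best restart).
#' @export
fit_subject_mle <- function(data, model_id, n_restarts = 10L, seed = 1L) {
  model_id <- match.arg(model_id, prl_models())
  pn <- param_bounds(model_id)$param
  K <- length(pn)
  tr <- data$trials
  ch <- as.integer(tr$choice == "B")
  oc <- as.numeric(tr$outcome)
  negll <- function(raw) {
    -sum(cpp_seq_loglik(model_code(model_id),
                        unname(transform_raw(raw, pn)), ch, oc))
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- rnorm(K, 0, 1.5)
    fit <- tryCatch(optim(init, negll, method = "BFGS",
                          control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimization restarts failed", call. = FALSE)
  list(params = transform_raw(best$par, pn), loglik = -best$value,
       convergence = best$convergence)
}

#' Pointwise log-likelihood matrix
#'
#' Evaluates each subject's full-sequence log-likelihood at every retained
#' posterior draw of that subject's own parameters. Subjects (not trials)
#' are the exchangeable units for model comparison.
#'
#' @param draws A `prl_draws` object.
#' @param subjects The subjects that were fit (list or `prl_cohort`);
#'   must match `draws$subject_ids`.
#' @return A draws x subjects matrix of log-likelihoods.
#' @export
pointwise_loglik <- function(draws, subjects) {
  if (inherits(subjects, "prl_cohort")) subjects <- subjects$subjects
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (!setequal(ids, draws$subject_ids) || anyDuplicated(ids)) {
    stop("subjects do not match the fitted draws", call. = FALSE)
  }
  subjects <- subjects[match(draws$subject_ids, ids)]
  out <- sapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    cpp_loglik_draws(model_code(draws$model_id),
                     subject_draws(draws, s$subject_id),
                     as.integer(s$trials$choice == "B"),
                     as.numeric(s$trials$outcome))
  })
  colnames(out) <- draws$subject_ids
  out
}
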