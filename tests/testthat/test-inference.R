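test_that("support transforms keep prior-predictive draws inside bounds", {
  set.seed(51)
  raw <- rnorm(1e5, 0, 3)  # wider than any realistic prior draw
  for (model in c("CU", "RP", "EWA_DL")) {
    b <- param_bounds(model)
    for (k in seq_len(nrow(b))) {
      v <- prlearn:::transform_raw(raw, rep(b$param[k], length(raw)))
      expect_true(all(v > b$lower[k] & v < b$upper[k]))
    }
  }
})

test_that("group fits are deterministic and respect parameter bounds", {
  spec <- group_spec("TD", "adults", "RW",
                     c(eta = 0.3, beta = 2, alpha = 0),
                     c(eta = 0.1, beta = 0.5, alpha = 0.1), 8)
  coh <- generate_cohort(list(spec), default_sched, seed = 4)
  cfg <- mcmc_config(chains = 2, iter = 200, warmup = 200, seed = 99,
                     on_nonconvergence = "warn")
  f1 <- suppressWarnings(fit_group(coh$subjects, "RW", cfg))
  f2 <- suppressWarnings(fit_group(coh$subjects, "RW", cfg))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$mu, f2$mu)
  b <- param_bounds("RW")
  for (k in seq_len(nrow(b))) {
    th <- f1$theta[, , , k]
    expect_true(all(th > b$lower[k] & th < b$upper[k]))
  }
  expect_true(all(f1$sigma > 0))
})

test_that("fit preconditions are enforced", {
  spec <- group_spec("TD", "adults", "RW", c(eta = 0.3, beta = 2, alpha = 0),
                     c(eta = 0.1, beta = 0.5, alpha = 0.1), 3)
  coh <- generate_cohort(list(spec), default_sched, seed = 4)
  expect_error(fit_group(coh$subjects[1], "RW"), "at least 2")
  mixed <- coh$subjects
  mixed[[2]]$diagnosis <- "ASD"
  expect_error(fit_group(mixed, "RW"), "group label")
})

test_that("tiny fits either converge or raise a diagnostic condition", {
  sched10 <- build_schedule(10, 6, 0.8, seed = 2)
  subs <- lapply(1:2, function(i) {
    simulate_agent("RW", c(eta = 0.3, beta = 2, alpha = 0), sched10,
                   seed = i, subject_id = paste0("s", i))
  })
  res <- tryCatch(
    fit_group(subs, "RW", mcmc_config(chains = 2, iter = 300, warmup = 300,
                                      seed = 3)),
    prl_convergence_error = function(e) e)
  if (inherits(res, "prl_convergence_error")) {
    expect_true(length(res$parameters) > 0)
  } else {
    expect_lte(max(res$diagnostics$rhat), 1.1)
  }
})

test_that("convergence statistics behave on known chain shapes", {
  set.seed(61)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(good), 1.02)
  expect_gt(ess_basic(good), 1500)
  # separated chains are flagged
  bad <- cbind(rnorm(500), rnorm(500) + 3)
  expect_gt(split_rhat(bad), 1.5)
  # strong autocorrelation shrinks the effective sample size
  ar <- matrix(0, 1000, 2)
  for (j in 1:2) for (i in 2:1000) ar[i, j] <- 0.95 * ar[i - 1, j] + rnorm(1)
  expect_lt(ess_basic(ar), 300)
})

test_that("subject-level MLE recovers parameters from long sequences", {
  sched500 <- build_schedule(500, 251, 0.8, seed = 8)
  ag <- simulate_agent("CU", c(eta = 0.2, beta = 3, alpha = 0), sched500,
                       seed = 12)
  fit <- fit_subject_mle(ag, "CU", n_restarts = 8, seed = 2)
  expect_lt(abs(fit$params[["eta"]] - 0.2), 0.05)
  # random responder: flat likelihood near n log 0.5
  ag0 <- simulate_agent("CU", c(eta = 0.2, beta = 1e-9, alpha = 0),
                        default_sched, seed = 13)
  fit0 <- fit_subject_mle(ag0, "CU", n_restarts = 5, seed = 2)
  expect_gte(fit0$loglik, 80 * log(0.5) - 1e-6)
  expect_lt(fit0$loglik, 80 * log(0.5) + 6)
  # more restarts can only improve the best log-likelihood
  l1 <- fit_subject_mle(ag, "CU", n_restarts = 1, seed = 5)$loglik
  l10 <- fit_subject_mle(ag, "CU", n_restarts = 10, seed = 5)$loglik
  expect_gte(l10, l1 - 1e-9)
})

test_that("pointwise log-likelihood aligns draws with subjects", {
  spec <- group_spec("TD", "adults", "RW", c(eta = 0.3, beta = 2, alpha = 0),
                     c(eta = 0.1, beta = 0.5, alpha = 0.1), 6)
  coh <- generate_cohort(list(spec), default_sched, seed = 4)
  fit <- suppressWarnings(
    fit_group(coh$subjects, "RW",
              mcmc_config(chains = 2, iter = 250, warmup = 250, seed = 5,
                          on_nonconvergence = "warn")))
  ll <- pointwise_loglik(fit, coh$subjects)
  expect_identical(dim(ll), c(500L, 6L))
  expect_true(all(ll <= 0))
  # one entry recomputed independently through the scalar likelihood
  th <- subject_draws(fit, coh$subjects[[3]]$subject_id)
  expect_equal(unname(ll[17, 3]),
               unname(sequence_loglik(coh$subjects[[3]], "RW", th[17, ])),
               tolerance = 1e-10)
  expect_error(pointwise_loglik(fit, coh$subjects[1:3]), "match")
})

test_that("hierarchical estimates shrink relative to subject-wise MLE", {
  spec <- group_spec("TD", "children", "CU",
                     c(eta = 0.193, beta = 1.202, alpha = -0.042),
                     c(eta = 0.087, beta = 0.892, alpha = 0.153), 25)
  coh <- generate_cohort(list(spec), default_sched, seed = 20)
  fit <- suppressWarnings(fit_group(coh$subjects, "CU", reduced_mcmc(seed = 21)))
  post_eta <- sapply(fit$subject_ids,
                     function(id) mean(subject_draws(fit, id)[, "eta"]))
  mle_eta <- sapply(coh$subjects, function(s) {
    fit_subject_mle(s, "CU", n_restarts = 4, seed = 3)$params[["eta"]]
  })
  expect_lt(sd(post_eta), sd(mle_eta))
})
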