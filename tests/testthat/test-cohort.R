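test_that("simulated agents are reproducible and well-formed", {
  a1 <- simulate_agent("RP", c(eta_rew = 0.4, eta_pun = 0.3, beta = 2,
                               alpha = 0), default_sched, seed = 5)
  a2 <- simulate_agent("RP", c(eta_rew = 0.4, eta_pun = 0.3, beta = 2,
                               alpha = 0), default_sched, seed = 5)
  expect_identical(a1$trials, a2$trials)
  expect_silent(validate_subject(a1))
  expect_identical(attr(a1, "model_id"), "RP")
  # outcomes agree with the schedule's anti-correlated delivery
  for (t in seq_len(80)) {
    expect_identical(a1$trials$outcome[t],
                     as.numeric(deliver_outcome(default_sched, t,
                                                a1$trials$choice[t],
                                                a1$trials$correct_stim[t])))
  }
})

test_that("choice stochasticity limits behave as expected", {
  # beta -> 0: random responder, long-run accuracy near 0.5
  accs <- sapply(1:300, function(s) {
    ag <- simulate_agent("CU", c(eta = 0.3, beta = 1e-9, alpha = 0),
                         default_sched, seed = s)
    mean(ag$trials$choice == ag$trials$correct_stim)
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.02)
  # high sensitivity near the optimal rate: clear reversal-phase learning
  accs_hi <- sapply(1:50, function(s) {
    ag <- simulate_agent("CU", c(eta = 0.25, beta = 4.9, alpha = 0),
                         default_sched, seed = s)
    mean(with(ag$trials, choice == correct_stim)[41:80])
  })
  expect_gt(mean(accs_hi), 0.7)
})

test_that("cohort generation respects group specs and stores ground truth", {
  specs <- default_group_specs(n_subjects = 20)
  coh <- generate_cohort(specs, default_sched, seed = 2)
  expect_length(coh$subjects, 120)
  expect_identical(length(unique(coh$ground_truth$subject_id)), 120L)
  # every subject has a ground-truth parameter row for its model
  gt <- coh$ground_truth
  for (spec in specs) {
    sub <- gt[gt$diagnosis == spec$diagnosis &
                gt$age_group == spec$age_group, ]
    expect_setequal(unique(sub$param), param_bounds(spec$model_id)$param)
    expect_identical(unique(sub$model_id), spec$model_id)
  }
})

test_that("drawn parameters concentrate at the spec means", {
  spec <- group_spec("TD", "children", "CU",
                     c(eta = 0.193, beta = 1.202, alpha = -0.042),
                     c(eta = 0.087, beta = 0.892, alpha = 0.153), 400)
  coh <- generate_cohort(list(spec), default_sched, seed = 8)
  gt <- coh$ground_truth
  eta_mean <- mean(gt$value[gt$param == "eta"])
  # truncation at 0 lifts the mean slightly; 3 SE band around the spec mean
  expect_lt(abs(eta_mean - 0.193), 3 * 0.087 / sqrt(400) + 0.01)
})

test_that("degenerate specs are handled explicitly", {
  sd0 <- group_spec("ASD", "adults", "RW",
                    c(eta = 0.3, beta = 2, alpha = 0),
                    c(eta = 0, beta = 0, alpha = 0), 5)
  coh <- generate_cohort(list(sd0), default_sched, seed = 1)
  vals <- coh$ground_truth
  for (p in c("eta", "beta", "alpha")) {
    expect_length(unique(vals$value[vals$param == p]), 1L)
  }
  # zero-size group contributes nothing, without error
  empty <- group_spec("TD", "adults", "RW", c(eta = 0.3, beta = 2, alpha = 0),
                      c(eta = 0.1, beta = 0.5, alpha = 0.1), 0)
  coh2 <- generate_cohort(list(empty, sd0), default_sched, seed = 1)
  expect_length(coh2$subjects, 5)
  # mass essentially outside the support is an error
  bad <- group_spec("TD", "adults", "RW",
                    c(eta = 0.999, beta = 2, alpha = 0),
                    c(eta = 1e-9, beta = 0.5, alpha = 0.1), 5)
  bad$means["eta"] <- 2  # bypass constructor check to probe the sampler
  expect_error(generate_cohort(list(bad), default_sched, seed = 1), "mass")
})

test_that("recovery sets match the recovery-analysis design", {
  coh <- recovery_set("CU", 40, default_sched, seed = 6)
  expect_length(coh$subjects, 40)
  for (s in coh$subjects) {
    expect_identical(nrow(s$trials), 80L)
    expect_silent(validate_subject(s))
  }
  expect_identical(unique(coh$ground_truth$model_id), "CU")
  # parameters drawn inside support
  gt <- coh$ground_truth
  b <- param_bounds("CU")
  for (k in seq_len(nrow(b))) {
    v <- gt$value[gt$param == b$param[k]]
    expect_true(all(v >= b$lower[k] & v <= b$upper[k]))
  }
  coh2 <- recovery_set("CU", 40, default_sched, seed = 7)
  expect_false(identical(coh$subjects[[1]]$trials$choice,
                         coh2$subjects[[1]]$trials$choice))
})

test_that("win-stay rises with value sensitivity in simulated cohorts", {
  mk <- function(beta, n = 200) {
    spec <- group_spec("TD", "adults", "CU",
                       c(eta = 0.3, beta = beta, alpha = 0),
                       c(eta = 0.05, beta = 0.01, alpha = 0.01), n)
    coh <- generate_cohort(list(spec), default_sched, seed = 17)
    mean(behavior_summary(coh)$win_stay, na.rm = TRUE)
  }
  expect_gt(mk(4.5), mk(0.01))
})

test_that("cohorts round-trip through trial-level CSV", {
  specs <- default_group_specs(n_subjects = 3)[c(1, 4)]
  coh <- generate_cohort(specs, default_sched, seed = 3)
  csv <- tempfile(fileext = ".csv")
  truth <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, csv, truth)
  back <- read_cohort_csv(csv, truth)
  expect_length(back$subjects, length(coh$subjects))
  for (i in seq_along(coh$subjects)) {
    expect_identical(back$subjects[[i]]$trials, coh$subjects[[i]]$trials)
    expect_identical(back$subjects[[i]]$subject_id,
                     coh$subjects[[i]]$subject_id)
  }
  expect_equal(back$ground_truth$value, coh$ground_truth$value)
  # malformed rows are rejected with the offending subject named
  df <- utils::read.csv(csv)
  df$choice[5] <- "Q"
  utils::write.csv(df, csv, row.names = FALSE)
  expect_error(read_cohort_csv(csv), "invalid stimulus")
})
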