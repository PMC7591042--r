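test_that("counterfactual update matches direct substitution", {
  st <- init_state("CU")
  up <- update_cu(st, "A", 1, 0.5)
  expect_equal(unname(up$V), c(0.5, -0.5), tolerance = 1e-12)
  expect_equal(update_cu(st, "A", 1, 0)$V, st$V)
  full <- update_cu(st, "B", -1, 1)
  expect_equal(unname(full$V), c(1, -1), tolerance = 1e-12)  # V_nc = -O, V_c = O
  expect_error(update_cu(st, "A", 1, 1.5), "eta")
})

test_that("reward-punishment update branches on the outcome sign", {
  st <- init_state("RP")
  st$V["A"] <- 0.5
  up <- update_rp(st, "A", -1, eta_rew = 0.9, eta_pun = 0.2)
  expect_equal(unname(up$V["A"]), 0.5 + 0.2 * (-1 - 0.5), tolerance = 1e-12)
  expect_equal(unname(up$V["A"]), 0.2, tolerance = 1e-12)
  # reward leaves the unchosen value untouched
  up2 <- update_rp(st, "A", 1, 0.4, 0.2)
  expect_identical(unname(up2$V["B"]), 0)
  expect_error(update_rp(st, "A", 0, 0.4, 0.2), "outcome")
})

test_that("equal reward/punishment rates collapse RP onto RW exactly", {
  set.seed(11)
  st_rp <- init_state("RP")
  st_rw <- init_state("RW")
  for (i in 1:50) {
    ch <- sample(c("A", "B"), 1)
    oc <- sample(c(-1, 1), 1)
    st_rp <- update_rp(st_rp, ch, oc, 0.37, 0.37)
    st_rw <- update_rw(st_rw, ch, oc, 0.37)
    expect_identical(st_rp$V, st_rw$V)
  }
})

test_that("EWA-DL reduces to known closed forms at corner decays", {
  # rho = 1, phi = 1: V is an incremental average of the outcomes together
  # with the initial pseudo-observation carried by n0 = 1, i.e.
  # V_t = (sum of outcomes) / (t + 1)
  st <- init_state("EWA_DL")
  outcomes <- c(1, -1, 1)
  for (i in seq_along(outcomes)) {
    st <- update_ewa(st, "A", outcomes[i], phi = 1, rho = 1)
    expect_equal(unname(st$V["A"]), sum(outcomes[1:i]) / (i + 1),
                 tolerance = 1e-12)
  }
  # first update is bounded for every rho: V1 = O / (rho + 1)
  for (rho in c(0, 0.5, 1)) {
    st1 <- update_ewa(init_state("EWA_DL"), "A", 1, phi = 0.7, rho = rho)
    expect_equal(unname(st1$V["A"]), 1 / (rho + 1), tolerance = 1e-12)
  }
  # rho = 0: leaky accumulator with fixed point 1 / (1 - phi) under constant reward
  for (phi in c(0.3, 0.7)) {
    st <- init_state("EWA_DL")
    for (i in 1:200) st <- update_ewa(st, "B", 1, phi = phi, rho = 0)
    expect_equal(unname(st$V["B"]), 1 / (1 - phi), tolerance = 1e-6)
  }
  # rho = 0, phi = 0: memoryless, value equals the last outcome
  st <- init_state("EWA_DL")
  st <- update_ewa(st, "A", 1, 0, 0)
  expect_identical(unname(st$V["A"]), 1)
  st <- update_ewa(st, "A", -1, 0, 0)
  expect_identical(unname(st$V["A"]), -1)
  # unchosen stimulus value and weight are frozen
  expect_identical(unname(st$V["B"]), 0)
  expect_identical(unname(st$n["B"]), 1)
})

test_that("Rescorla-Wagner updates only the chosen value and converges", {
  st <- init_state("RW")
  expect_equal(unname(update_rw(st, "A", 1, 0.3)$V), c(0.3, 0),
               tolerance = 1e-12)
  expect_equal(update_rw(st, "A", 1, 0)$V, st$V)
  v_prev <- 0
  for (i in 1:100) {
    st <- update_rw(st, "A", 1, 0.25)
    expect_gte(unname(st$V["A"]), v_prev)
    v_prev <- unname(st$V["A"])
  }
  expect_equal(v_prev, 1, tolerance = 1e-10)
})

test_that("softmax choice rule matches its closed form and is stable", {
  st <- init_state("CU")
  for (b in c(0.1, 1, 4.9)) expect_equal(choice_prob(st, b, 0), 0.5)
  st$V["A"] <- 1
  expect_equal(choice_prob(st, 2, 0), 1 / (1 + exp(-2)), tolerance = 1e-12)
  # value difference equal to the indifference point gives 0.5 for any beta
  st$V <- c(A = 0.3, B = 0.1)
  for (b in c(0.5, 3)) expect_equal(choice_prob(st, b, 0.2), 0.5)
  # complementarity and numerical stability at extreme arguments
  for (va in c(-1e4, -1, 0, 1, 1e4)) {
    st$V <- c(A = va, B = 0)
    pA <- choice_prob(st, 5, 0.4)
    st_flip <- st; st_flip$V <- c(A = 0, B = va)
    pB_flip <- 1 - choice_prob(st_flip, 5, -0.4)
    expect_true(is.finite(pA) && pA >= 0 && pA <= 1)
    expect_equal(pA + (1 - pA), 1)
    expect_equal(pA, pB_flip, tolerance = 1e-12)
  }
})

test_that("choice probability is monotone in value difference and beta", {
  st <- init_state("CU")
  dv <- seq(-2, 2, by = 0.25)
  p <- sapply(dv, function(d) { st$V["A"] <- d; choice_prob(st, 2, 0) })
  expect_true(all(diff(p) > 0))
  st$V["A"] <- 1  # above the indifference point
  pb <- sapply(seq(0.2, 4.8, by = 0.2),
               function(b) choice_prob(st, b, 0.1))
  expect_true(all(diff(pb) > 0))
})

test_that("values stay in [-1, 1] for RW, CU and RP with unit outcomes", {
  set.seed(21)
  for (rep in 1:20) {
    st_set <- list(RW = init_state("RW"), CU = init_state("CU"),
                   RP = init_state("RP"))
    rates <- runif(4)
    for (i in 1:60) {
      ch <- sample(c("A", "B"), 1)
      oc <- sample(c(-1, 1), 1)
      st_set$RW <- update_rw(st_set$RW, ch, oc, rates[1])
      st_set$CU <- update_cu(st_set$CU, ch, oc, rates[2])
      st_set$RP <- update_rp(st_set$RP, ch, oc, rates[3], rates[4])
      for (st in st_set) expect_true(all(abs(st$V) <= 1 + 1e-12))
    }
  }
})

test_that("EWA experience weights stay within their analytic envelope", {
  set.seed(22)
  for (rep in 1:10) {
    rho <- runif(1, 0, 0.99)
    st <- init_state("EWA_DL")
    for (i in 1:100) {
      st <- update_ewa(st, sample(c("A", "B"), 1), sample(c(-1, 1), 1),
                       runif(1), rho)
      expect_true(all(st$n >= 0 & st$n <= 1 / (1 - rho) + 1e-9))
    }
  }
})

test_that("sequence log-likelihood has the right limits and ordering", {
  ag <- simulate_agent("CU", c(eta = 0.3, beta = 2, alpha = 0),
                       default_sched, seed = 4)
  # beta -> 0: every trial contributes log(0.5)
  ll0 <- sequence_loglik(ag, "CU", c(eta = 0.3, beta = 1e-12, alpha = 0))
  expect_equal(ll0, 80 * log(0.5), tolerance = 1e-6)
  # per-trial vector sums to the total
  p <- c(eta = 0.25, beta = 1.5, alpha = 0.1)
  expect_equal(sum(sequence_loglik(ag, "CU", p, per_trial = TRUE)),
               sequence_loglik(ag, "CU", p))
  # trial order matters (state dependence)
  shuf <- ag
  set.seed(9)
  perm <- sample(nrow(ag$trials))
  shuf$trials <- ag$trials[perm, ]
  shuf$trials$trial <- seq_len(nrow(ag$trials))
  expect_false(isTRUE(all.equal(sequence_loglik(shuf, "CU", p),
                                sequence_loglik(ag, "CU", p))))
})

test_that("likelihood matches the naive per-trial oracle across models", {
  set.seed(31)
  for (model in prl_models()) {
    for (rep in 1:5) {
      p <- random_params(model)
      ag <- simulate_agent(model, p, default_sched, seed = rep + 100)
      expect_equal(sequence_loglik(ag, model, p),
                   r_seq_loglik(ag, model, p), tolerance = 1e-10)
    }
  }
})
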