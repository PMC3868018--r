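test_that("log-likelihood satisfies its basic identities", {
  fx <- fixture_record()
  params <- parameter_vector(1.7, 0.9, 0.2)
  # a single coin-flip trial contributes ln 0.5
  one <- fx$record[1, , drop = FALSE]
  one$choice <- "G"
  b1 <- fx$beliefs_reward[1, , drop = FALSE]
  b2 <- fx$beliefs_social[1, , drop = FALSE]
  ll_half <- log_likelihood(parameter_vector(0, 0, 0), one, b1, b2)
  expect_equal(ll_half, log(0.5), tolerance = 1e-12)

  # additivity over a concatenation
  n <- nrow(fx$record)
  idx1 <- 1:(n %/% 2); idx2 <- (n %/% 2 + 1):n
  ll_all <- log_likelihood(params, fx$record, fx$beliefs_reward,
                           fx$beliefs_social)
  ll_parts <-
    log_likelihood(params, fx$record[idx1, ], fx$beliefs_reward[idx1, ],
                   fx$beliefs_social[idx1, ]) +
    log_likelihood(params, fx$record[idx2, ], fx$beliefs_reward[idx2, ],
                   fx$beliefs_social[idx2, ])
  expect_equal(ll_all, ll_parts, tolerance = 1e-10)
})

test_that("likelihood matches the independent trial-by-trial oracle", {
  fx <- fixture_record()
  set.seed(99)
  for (i in 1:20) {
    gs <- runif(1, 0.01, 10); gr <- runif(1, 0.01, 10)
    be <- runif(1, 0.01, 2)
    got <- log_likelihood(parameter_vector(gs, gr, be), fx$record,
                          fx$beliefs_reward, fx$beliefs_social)
    want <- oracle_ll(gs, gr, be, fx$record, fx$beliefs_reward$estimate,
                      fx$beliefs_social$estimate)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the vectorized likelihood grid equals pointwise evaluation", {
  fx <- fixture_record()
  gv <- c(0.05, 0.5, 2, 8)
  bv <- c(0.02, 0.3, 1.5)
  surf <- infoweight:::ll_surface(fx$record, fx$beliefs_reward,
                                  fx$beliefs_social, gv, bv)
  for (i in seq_along(gv)) for (j in seq_along(gv)) for (b in seq_along(bv)) {
    want <- log_likelihood(parameter_vector(gv[i], gv[j], bv[b]), fx$record,
                           fx$beliefs_reward, fx$beliefs_social)
    expect_lt(abs(surf[i, j, b] - want), 1e-7)
  }
})

test_that("posterior normalizes, stays in bounds, and reports uncertainty", {
  fx <- fixture_record()
  post <- fit_posterior(fx$record, fx$beliefs_reward, fx$beliefs_social,
                        fit_grid(20))
  for (m in post$marginals) expect_equal(sum(m), 1, tolerance = 1e-10)
  expect_true(all(post$point_estimates >= 0.01 &
                    post$point_estimates <= 10))
  expect_true(all(post$posterior_sds >= 0))
  expect_true(is.finite(post$log_evidence))
  expect_true(is.finite(post$ll_at_estimate))
})

test_that("coin-flip choices with equal magnitudes pin beta to the low edge", {
  cfg <- schedule_config(
    n_trials = 120,
    reward_prob_blocks = data.frame(length = 120, p = 0.8),
    advice_fidelity_blocks = data.frame(length = 120, p = 0.75),
    magnitude_low = 50, magnitude_high = 50, seed = 41)
  sch <- generate_schedule(cfg)
  oc <- extract_outcomes(sch)
  g <- small_grid(8)
  br <- track_bayes(oc$reward_outcomes, g)
  bs <- track_bayes(oc$advice_outcomes, g)
  rec <- sch
  rec$choice <- withr::with_seed(43, sample(c("G", "B"), 120, TRUE))
  class(rec) <- c("choice_record", class(sch))
  post <- fit_posterior(rec, br, bs, fit_grid(25))
  mb <- post$marginals$beta
  # mass piles up at the lower grid edge: the bottom fifth of nodes holds
  # far more than its uniform share and contains the marginal mode
  expect_gt(sum(mb[1:5]), 2 * 5 / 25)
  expect_lte(which.max(mb), 5)
})

test_that("point estimates are stable under grid refinement", {
  fx <- fixture_record()
  coarse <- fit_posterior(fx$record, fx$beliefs_reward, fx$beliefs_social,
                          fit_grid(30))
  fine <- fit_posterior(fx$record, fx$beliefs_reward, fx$beliefs_social,
                        fit_grid(60))
  rel <- abs(fine$point_estimates - coarse$point_estimates) /
    fine$point_estimates
  expect_true(all(rel < 0.05))
})

test_that("posterior spread contracts as trials accumulate", {
  g <- learner_grid(12, 12, 12)
  sds <- vapply(c(50, 290, 1000), function(n) {
    cfg <- schedule_config(
      n_trials = n,
      reward_prob_blocks = data.frame(
        length = c(n %/% 3, n %/% 3, n - 2 * (n %/% 3)), p = c(0.8, 0.2, 0.8)),
      advice_fidelity_blocks = data.frame(
        length = c(n %/% 2, n - n %/% 2), p = c(0.75, 0.25)),
      seed = n)
    sch <- generate_schedule(cfg)
    rec <- simulate_agent(agent_spec(2, 1, 0.3, seed = n + 1), sch, g)
    bel <- attr(rec, "beliefs")
    post <- fit_posterior(rec, bel$reward, bel$social, fit_grid(20))
    mean(post$posterior_sds[c("gamma_social", "gamma_reward")])
  }, 0)
  expect_true(all(diff(sds) < 0))
})

test_that("predictive accuracy scores argmax agreement with half for ties", {
  fx <- fixture_record()
  trace <- attr(fx$record, "trace")
  acc <- predictive_accuracy(fx$record, trace)
  expect_gte(acc, 0)
  expect_lte(acc, 1)
  # hand-built check including an exact tie
  rec <- fx$record[1:3, ]
  rec$choice <- c("G", "B", "G")
  tr <- trace[1:3, ]
  tr$p_green_choice <- c(0.9, 0.2, 0.5)
  expect_equal(predictive_accuracy(rec, tr), (1 + 1 + 0.5) / 3)
})

test_that("near-deterministic agents are predicted almost perfectly", {
  sch <- generate_schedule(schedule_config(seed = 55))
  g <- learner_grid(15, 15, 15)
  rec <- simulate_agent(agent_spec(2, 2, 10, seed = 56), sch, g)
  bel <- attr(rec, "beliefs")
  post <- fit_posterior(rec, bel$reward, bel$social, fit_grid(25))
  trace <- policy_trace(as.list(post$point_estimates), rec, bel$reward,
                        bel$social)
  expect_gt(predictive_accuracy(rec, trace), 0.95)
})

test_that("coin-flip choices are predicted at chance", {
  accs <- vapply(1:5, function(s) {
    sch <- generate_schedule(schedule_config(seed = 100 + s))
    rec <- sch
    rec$choice <- withr::with_seed(200 + s, sample(c("G", "B"), 290, TRUE))
    class(rec) <- c("choice_record", class(sch))
    oc <- extract_outcomes(sch)
    g <- small_grid(8)
    br <- track_bayes(oc$reward_outcomes, g)
    bs <- track_bayes(oc$advice_outcomes, g)
    post <- fit_posterior(rec, br, bs, fit_grid(20))
    trace <- policy_trace(as.list(post$point_estimates), rec, br, bs)
    predictive_accuracy(rec, trace)
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.03)
  expect_true(all(abs(accs - 0.5) < 0.1))
})

test_that("information criteria follow their formulas", {
  fx <- fixture_record()
  mc <- compare_models(fx$record, fx$beliefs_reward, fx$beliefs_social,
                       grid = fit_grid(12),
                       alpha_grid = c(0.1, 0.4))
  for (m in list(mc$bayes_volatility, mc$rw_fixed)) {
    expect_equal(m$bic, m$n_params * log(mc$n_trials) - 2 * m$ll)
    expect_equal(m$aic, 2 * m$n_params - 2 * m$ll)
  }
  expect_equal(mc$bayes_volatility$n_params, 3L)
  expect_equal(mc$rw_fixed$n_params, 5L)
  # equal log-likelihoods would differ by exactly 2 ln(n) in BIC
  expect_equal((5 - 3) * log(mc$n_trials),
               (mc$rw_fixed$bic + 2 * mc$rw_fixed$ll) -
                 (mc$bayes_volatility$bic + 2 * mc$bayes_volatility$ll))
})
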