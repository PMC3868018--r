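# Small fixtures built in code.

small_schedule <- function(seed = 11, n_trials = 60) {
  schedule_config(
    n_trials = n_trials,
    reward_prob_blocks = data.frame(length = c(n_trials %/% 2,
                                               n_trials - n_trials %/% 2),
                                    p = c(0.8, 0.2)),
    advice_fidelity_blocks = data.frame(length = n_trials, p = 0.75),
    seed = seed) |> generate_schedule()
}

small_grid <- function(pts = 6) {
  learner_grid(pts, pts, pts)
}

# A modest simulated record plus its Bayesian beliefs, shared across tests.
fixture_record <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sch <- generate_schedule(schedule_config(seed = 303))
      oc <- extract_outcomes(sch)
      g <- learner_grid()
      br <- track_bayes(oc$reward_outcomes, g)
      bs <- track_bayes(oc$advice_outcomes, g)
      rec <- simulate_agent(agent_spec(2, 1, 0.3, seed = 404), sch, g)
      cache <<- list(schedule = sch, record = rec, beliefs_reward = br,
                     beliefs_social = bs)
    }
    cache
  }
})
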