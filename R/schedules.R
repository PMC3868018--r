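#' Default reward-probability block structure
#'
#' The true probability that the green option is rewarded is piecewise
#' constant with reversals between 0.8 and 0.2. The published task states only
#' that the probability "underwent several reversals"; this default uses five
#' blocks of 40-80 trials summing to 290, chosen to mimic the shape of the
#' published probability trace. It is a documented guess, not a
#' reconstruction, and is fully configurable.
#'
#' @return A data.frame with columns `length` (trials) and `p` (probability).
#' @export
default_reward_blocks <- function() {
  data.frame(length = c(60, 55, 60, 55, 60),
             p = c(0.8, 0.2, 0.8, 0.2, 0.8))
}

#' Default advice-fidelity block structure
#'
#' The probability that the partner's advice points to the correct option,
#' piecewise constant between 0.75 and 0.25, varying independently of the
#' reward process. Four blocks of 70-75 trials summing to 290.
#'
#' @return A data.frame with columns `length` and `p`.
#' @export
default_advice_blocks <- function() {
  data.frame(length = c(70, 75, 70, 75),
             p = c(0.75, 0.25, 0.75, 0.25))
}

as_blocks <- function(blocks, what) {
  if (is.data.frame(blocks)) {
    b <- blocks
  } else if (is.list(blocks)) {
    b <- do.call(rbind, lapply(blocks, function(x) {
      data.frame(length = x[[1]], p = x[[2]])
    }))
  } else {
    stop(what, " must be a data.frame(length, p) or list of (length, p) pairs",
         call. = FALSE)
  }
  if (!all(c("length", "p") %in% names(b))) {
    stop(what, " must have columns 'length' and 'p'", call. = FALSE)
  }
  b
}

#' Task schedule configuration
#'
#' Describes the generative structure of the advice-augmented two-option
#' probabilistic task: 290 trials by default, reward magnitudes drawn
#' uniformly on the integers 1-100, and two independent piecewise-constant
#' probability processes (reward and advice fidelity) with reversals.
#'
#' @param n_trials Number of trials (default 290).
#' @param reward_prob_blocks Blocks for the probability that green is the
#'   rewarded option: data.frame with columns `length`, `p` (lengths must sum
#'   to `n_trials`).
#' @param advice_fidelity_blocks Blocks for the probability that the advice
#'   is correct; same format.
#' @param magnitude_low,magnitude_high Inclusive integer bounds for per-trial
#'   reward magnitudes (points).
#' @param seed Integer seed; the schedule is fully reproducible from it.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(n_trials = 290,
                            reward_prob_blocks = default_reward_blocks(),
                            advice_fidelity_blocks = default_advice_blocks(),
                            magnitude_low = 1,
                            magnitude_high = 100,
                            seed = 1L) {
  rb <- as_blocks(reward_prob_blocks, "reward_prob_blocks")
  ab <- as_blocks(advice_fidelity_blocks, "advice_fidelity_blocks")
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  if (sum(rb$length) != n_trials) {
    stop("reward_prob_blocks lengths sum to ", sum(rb$length),
         ", expected n_trials = ", n_trials, call. = FALSE)
  }
  if (sum(ab$length) != n_trials) {
    stop("advice_fidelity_blocks lengths sum to ", sum(ab$length),
         ", expected n_trials = ", n_trials, call. = FALSE)
  }
  if (any(rb$p < 0 | rb$p > 1) || any(ab$p < 0 | ab$p > 1)) {
    stop("block probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (magnitude_low < 1) stop("magnitude_low must be >= 1", call. = FALSE)
  if (magnitude_high < magnitude_low) {
    stop("magnitude_high must be >= magnitude_low", call. = FALSE)
  }
  structure(list(n_trials = as.integer(n_trials),
                 reward_prob_blocks = rb,
                 advice_fidelity_blocks = ab,
                 magnitude_low = as.integer(magnitude_low),
                 magnitude_high = as.integer(magnitude_high),
                 seed = as.integer(seed)),
            class = "schedule_config")
}

#' Generate a trial schedule
#'
#' Draws, per trial, the correct color (Bernoulli in the true reward
#' probability), whether the advice is correct (Bernoulli in the true advice
#' fidelity, independently), and integer reward magnitudes for both options
#' (uniform on `[magnitude_low, magnitude_high]`). The advice color is then
#' derived from the correct color and whether the advice is correct on that
#' trial. The two outcome processes are independent by construction, matching
#' the task design.
#'
#' @param config A [schedule_config()].
#' @return A data.frame of class `trial_schedule` with one row per trial and
#'   columns `trial`, `p_green_true`, `p_social_true`, `r_green`, `r_blue`,
#'   `correct`, `advice`, `advice_correct`. Colors are coded `"G"`/`"B"`.
#' @export
generate_schedule <- function(config) {
  if (!inherits(config, "schedule_config")) {
    stop("config must be a schedule_config", call. = FALSE)
  }
  n <- config$n_trials
  p_green <- rep(config$reward_prob_blocks$p, config$reward_prob_blocks$length)
  p_social <- rep(config$advice_fidelity_blocks$p,
                  config$advice_fidelity_blocks$length)
  lo <- config$magnitude_low
  hi <- config$magnitude_high
  withr::with_seed(config$seed, {
    correct <- ifelse(stats::runif(n) < p_green, "G", "B")
    advice_correct <- as.integer(stats::runif(n) < p_social)
    r_green <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
    r_blue <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  })
  advice <- ifelse(advice_correct == 1L, correct, other_color(correct))
  out <- data.frame(trial = seq_len(n),
                    p_green_true = p_green,
                    p_social_true = p_social,
                    r_green = r_green,
                    r_blue = r_blue,
                    correct = correct,
                    advice = advice,
                    advice_correct = advice_correct,
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_schedule", "data.frame")
  attr(out, "config") <- config
  out
}

#' Extract binary outcome sequences from a schedule
#'
#' The task is full-information: the correct color is revealed on every trial
#' regardless of the choice, so both learning sequences are properties of the
#' schedule alone and never depend on a subject's choices.
#'
#' @param schedule A `trial_schedule` (or choice record carrying the same
#'   columns).
#' @return A list with `reward_outcomes` (1 = green was correct) and
#'   `advice_outcomes` (1 = advice matched the correct color), both 0/1
#'   integer vectors of length `n_trials`.
#' @export
extract_outcomes <- function(schedule) {
  req <- c("correct", "advice", "advice_correct")
  miss <- setdiff(req, names(schedule))
  if (length(miss)) {
    stop("schedule is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  correct <- normalize_color(schedule$correct)
  advice <- normalize_color(schedule$advice)
  derived <- as.integer(advice == correct)
  if (!all(derived == schedule$advice_correct)) {
    stop("advice_correct is inconsistent with advice and correct columns",
         call. = FALSE)
  }
  list(reward_outcomes = as.integer(correct == "G"),
       advice_outcomes = derived)
}
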