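#' Parameter vector of the information-weighting choice model
#'
#' Three per-subject free parameters: `gamma_social` and `gamma_reward`
#' control how strongly the tracked advice-fidelity and reward-history
#' probabilities influence choice (large gamma amplifies a probability toward
#' the extremes, small gamma flattens it toward 0.5 so current reward
#' magnitudes dominate), and `beta` is the softmax inverse temperature
#' governing choice stochasticity.
#'
#' @param gamma_social,gamma_reward Nonnegative information-use weights.
#' @param beta Nonnegative inverse temperature.
#' @return A named list of class `parameter_vector`.
#' @export
parameter_vector <- function(gamma_social, gamma_reward, beta) {
  vals <- c(gamma_social = gamma_social, gamma_reward = gamma_reward,
            beta = beta)
  if (anyNA(vals) || any(vals < 0)) {
    stop("all parameters must be nonnegative", call. = FALSE)
  }
  structure(as.list(vals), class = "parameter_vector")
}

as_params <- function(params) {
  p <- as.list(params)
  req <- c("gamma_social", "gamma_reward", "beta")
  miss <- setdiff(req, names(p))
  if (length(miss)) {
    stop("params is missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  p[req]
}

#' Subjective probability transform
#'
#' Maps a tracked ("objective") probability `p` to the subjective probability
#' `1 / (1 + exp(-gamma * (p - 0.5)))`. The transform is centered at 0.5:
#' large `gamma` amplifies departures from 0.5 toward the extremes, while
#' `gamma` near 0 compresses everything toward 0.5 (the information is
#' ignored). `subjective_probability(0.5, gamma)` is 0.5 for every gamma.
#'
#' @param p Probability (or vector) in [0, 1].
#' @param gamma Nonnegative weight.
#' @return Subjective probability in (0, 1).
#' @export
subjective_probability <- function(p, gamma) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (any(gamma < 0)) stop("gamma must be nonnegative", call. = FALSE)
  stats::plogis(gamma * (p - 0.5))
}

#' Combine reward-history and advice information
#'
#' Bayes-rule combination of the subjective reward probability and the
#' subjective advice fidelity into an overall probability that green is
#' rewarded. When the partner suggests green,
#' `q = ps*pg / (ps*pg + (1-ps)*(1-pg))`; when the partner suggests blue the
#' Bayes-consistent mirror `q = (1-ps)*pg / ((1-ps)*pg + ps*(1-pg))` is used.
#' Uninformative advice (`ps = 0.5`) leaves `pg` unchanged.
#'
#' The published blue-advice formula does not normalize against its own
#' denominator (a typographical slip); the default here is the consistent
#' mirror, and `as_printed = TRUE` reproduces the literal printed form for
#' auditability.
#'
#' @param p_hat_social Subjective advice-fidelity probability (vectorized).
#' @param p_hat_green Subjective reward probability for green.
#' @param advice Advice color(s), `"G"`/`"B"`.
#' @param as_printed Use the literal (unnormalized) blue-advice numerator.
#' @param eps Clamp applied to inputs at exactly 0 or 1 (default 1e-9).
#' @return Combined probability in (0, 1).
#' @export
combine_advice <- function(p_hat_social, p_hat_green, advice,
                           as_printed = FALSE, eps = 1e-9) {
  ps <- clamp_prob(p_hat_social, eps)
  pg <- clamp_prob(p_hat_green, eps)
  g <- normalize_color(advice) == "G"
  if (as_printed) {
    # literal printed blue-advice form: numerator ps*pg over the mirror
    # denominator (does not normalize; audit mode only)
    num <- ps * pg
    den <- ifelse(g, ps * pg + (1 - ps) * (1 - pg),
                  ps * (1 - pg) + (1 - ps) * pg)
  } else {
    num <- ifelse(g, ps * pg, (1 - ps) * pg)
    den <- ifelse(g, ps * pg + (1 - ps) * (1 - pg),
                  (1 - ps) * pg + ps * (1 - pg))
  }
  num / den
}

#' Expected value of each option
#'
#' `V_green = q * r_green`, `V_blue = (1 - q) * r_blue` where `q` is the
#' combined probability that green is rewarded and the `r`s are the points on
#' offer. Because magnitudes vary independently of probabilities, the less
#' likely color can carry the higher expected value.
#'
#' @param q_hat Combined probability green is rewarded.
#' @param r_green,r_blue Nonnegative reward magnitudes (points).
#' @return A list with numeric vectors `v_green` and `v_blue`.
#' @export
expected_values <- function(q_hat, r_green, r_blue) {
  if (any(r_green < 0) || any(r_blue < 0)) {
    stop("reward magnitudes must be nonnegative", call. = FALSE)
  }
  list(v_green = q_hat * r_green, v_blue = (1 - q_hat) * r_blue)
}

#' Softmax choice probability
#'
#' `P(green) = 1 / (1 + exp(-beta * (v_green - v_blue)))`; `P(blue)` is its
#' complement. `beta = 0` gives indifference (0.5) regardless of values.
#' Computed through a numerically stable signed formulation.
#'
#' @param v_green,v_blue Expected values.
#' @param beta Nonnegative inverse temperature.
#' @return Probability of choosing green.
#' @export
choice_probability <- function(v_green, v_blue, beta) {
  if (any(beta < 0)) stop("beta must be nonnegative", call. = FALSE)
  stats::plogis(beta * (v_green - v_blue))
}

#' Per-trial choice policy trace
#'
#' Applies the full model trial by trial: subjective transforms of both
#' tracked probabilities, Bayes combination with the trial's advice, expected
#' values from the trial's magnitudes, and the softmax. Deterministic given
#' its inputs; belief trajectories must be predictive (pre-feedback), which
#' [track_bayes()] and [track_rw()] guarantee.
#'
#' @param params Parameters (a [parameter_vector()] or named list with
#'   `gamma_social`, `gamma_reward`, `beta`).
#' @param schedule A `trial_schedule` (or choice record).
#' @param beliefs_reward,beliefs_social Belief trajectories for the reward
#'   and advice processes, same length as the schedule.
#' @param as_printed Passed to [combine_advice()].
#' @return A data.frame of class `choice_policy_trace` with columns `trial`,
#'   `p_hat_social`, `p_hat_green`, `q_hat`, `v_green`, `v_blue`,
#'   `p_green_choice`.
#' @export
policy_trace <- function(params, schedule, beliefs_reward, beliefs_social,
                         as_printed = FALSE) {
  p <- as_params(params)
  n <- nrow(schedule)
  if (nrow(beliefs_reward) != n || nrow(beliefs_social) != n) {
    stop("belief trajectories must match the schedule length", call. = FALSE)
  }
  ps_hat <- subjective_probability(beliefs_social$estimate, p$gamma_social)
  pg_hat <- subjective_probability(beliefs_reward$estimate, p$gamma_reward)
  q <- combine_advice(ps_hat, pg_hat, schedule$advice, as_printed = as_printed)
  ev <- expected_values(q, schedule$r_green, schedule$r_blue)
  pc <- choice_probability(ev$v_green, ev$v_blue, p$beta)
  out <- data.frame(trial = schedule$trial,
                    p_hat_social = ps_hat,
                    p_hat_green = pg_hat,
                    q_hat = q,
                    v_green = ev$v_green,
                    v_blue = ev$v_blue,
                    p_green_choice = pc)
  class(out) <- c("choice_policy_trace", "data.frame")
  out
}
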