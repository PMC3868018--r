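#' Log-spaced parameter grid for posterior integration
#'
#' All three parameters range over [0.01, 10] and the grid is evaluated in
#' log space, so the (uniform-over-grid) prior is log-uniform.
#'
#' @param points_per_dim Grid points per parameter (default 50, minimum 10).
#' @param bounds Positive parameter bounds (default `c(0.01, 10)`).
#' @return An object of class `fit_grid` with the parameter values and their
#'   logs.
#' @export
fit_grid <- function(points_per_dim = 50, bounds = c(0.01, 10)) {
  if (points_per_dim < 10) stop("points_per_dim must be >= 10", call. = FALSE)
  if (any(bounds <= 0) || bounds[1] >= bounds[2]) {
    stop("bounds must be positive and increasing", call. = FALSE)
  }
  lv <- seq(log(bounds[1]), log(bounds[2]), length.out = points_per_dim)
  structure(list(values = exp(lv), log_values = lv, bounds = bounds,
                 points_per_dim = as.integer(points_per_dim)),
            class = "fit_grid")
}

#' Log-likelihood of a choice record under the model
#'
#' Sum over trials of the log probability the policy trace assigns to the
#' observed choice, with a floor of `prob_floor` on per-trial probabilities
#' to keep the sum finite.
#'
#' @param params Model parameters.
#' @param record A `choice_record`.
#' @param beliefs_reward,beliefs_social Predictive belief trajectories
#'   computed from the schedule's outcome sequences (choice-independent).
#' @param prob_floor Per-trial probability floor (default 1e-9).
#' @return A single finite number.
#' @export
log_likelihood <- function(params, record, beliefs_reward, beliefs_social,
                           prob_floor = 1e-9) {
  if (is.null(record$choice) || anyNA(record$choice)) {
    stop("record must contain a complete choice column", call. = FALSE)
  }
  trace <- policy_trace(params, record, beliefs_reward, beliefs_social)
  chose_green <- normalize_color(record$choice) == "G"
  p <- ifelse(chose_green, trace$p_green_choice, 1 - trace$p_green_choice)
  sum(log(pmax(p, prob_floor)))
}

# Log-likelihood over a full (gamma_social x gamma_reward x beta) grid.
# Uses the identity logit(q) = gamma_reward*(p_green-0.5) +/-
# gamma_social*(p_social-0.5) (+ for green advice, - for blue), which is
# algebraically equal to the subjective-transform + Bayes-combination chain;
# tests assert the equality against the literal composition.
ll_surface <- function(record, beliefs_reward, beliefs_social,
                       gamma_values, beta_values, prob_floor = 1e-9) {
  n <- nrow(record)
  if (nrow(beliefs_reward) != n || nrow(beliefs_social) != n) {
    stop("belief trajectories must match the record length", call. = FALSE)
  }
  x <- beliefs_reward$estimate - 0.5
  a <- ifelse(normalize_color(record$advice) == "G", 1, -1)
  y <- a * (beliefs_social$estimate - 0.5)
  s <- ifelse(normalize_color(record$choice) == "G", 1, -1)
  G <- length(gamma_values)
  Gx <- gamma_values %o% x        # rows index gamma_reward
  Gy <- gamma_values %o% y        # rows index gamma_social
  # (G^2) x n matrix; pair index = (gamma_social fastest, gamma_reward slow)
  L <- Gy[rep(seq_len(G), times = G), , drop = FALSE] +
    Gx[rep(seq_len(G), each = G), , drop = FALSE]
  Q <- stats::plogis(L)
  RG <- rep(record$r_green, each = G * G)
  RB <- rep(record$r_blue, each = G * G)
  D <- Q * RG - (1 - Q) * RB
  S <- D * rep(s, each = G * G)
  floor_ll <- log(prob_floor)
  ll <- matrix(0, G * G, length(beta_values))
  for (bi in seq_along(beta_values)) {
    Z <- beta_values[bi] * S
    lp <- pmax(log_plogis(Z), floor_ll)
    ll[, bi] <- rowSums(lp)
  }
  array(ll, dim = c(G, G, length(beta_values)))
}

#' Fit the choice model by grid-based Bayesian integration
#'
#' Evaluates the log-likelihood at every node of the 3-D log-spaced grid,
#' adds the (log-uniform) prior, and normalizes by log-sum-exp. Marginals are
#' obtained by summation; the point estimate of each parameter is its
#' marginal posterior mean computed in log space and exponentiated, and the
#' reported posterior SD is on the natural parameter scale, which is the
#' fitting-reliability measure the method is chosen for.
#'
#' @param record A `choice_record`.
#' @param beliefs_reward,beliefs_social Predictive belief trajectories.
#' @param grid A [fit_grid()].
#' @param prob_floor Per-trial probability floor inside the likelihood.
#' @return An object of class `parameter_posterior`: `point_estimates`,
#'   `posterior_sds` (named: gamma_social, gamma_reward, beta), `marginals`
#'   (each summing to 1), `log_evidence`, `ll_max`, `map_estimates` (grid
#'   node of maximum likelihood), `ll_at_estimate`, `grid`.
#' @export
fit_posterior <- function(record, beliefs_reward, beliefs_social,
                          grid = fit_grid(), prob_floor = 1e-9) {
  llA <- ll_surface(record, beliefs_reward, beliefs_social,
                    grid$values, grid$values, prob_floor)
  lse <- logsumexp(llA)
  if (!is.finite(lse)) {
    stop("likelihood is zero everywhere on the grid (", length(llA),
         " nodes; max LL = ", max(llA), ")", call. = FALSE)
  }
  w <- exp(llA - lse)            # posterior weights under the uniform prior
  marg <- list(gamma_social = apply(w, 1, sum),
               gamma_reward = apply(w, 2, sum),
               beta = apply(w, 3, sum))
  marg <- lapply(marg, function(m) m / sum(m))
  point <- vapply(marg, function(m) exp(sum(m * grid$log_values)), 0)
  sds <- vapply(marg, function(m) {
    mu <- sum(m * grid$values)
    sqrt(max(0, sum(m * grid$values^2) - mu^2))
  }, 0)
  imax <- arrayInd(which.max(llA), dim(llA))
  map_est <- c(gamma_social = grid$values[imax[1]],
               gamma_reward = grid$values[imax[2]],
               beta = grid$values[imax[3]])
  est <- parameter_vector(point[["gamma_social"]], point[["gamma_reward"]],
                          point[["beta"]])
  structure(list(point_estimates = point,
                 posterior_sds = sds,
                 marginals = marg,
                 log_evidence = lse - log(length(llA)),
                 ll_max = max(llA),
                 map_estimates = map_est,
                 ll_at_estimate = log_likelihood(est, record, beliefs_reward,
                                                 beliefs_social, prob_floor),
                 grid = grid),
            class = "parameter_posterior")
}

#' @export
print.parameter_posterior <- function(x, ...) {
  cat("Grid posterior (", x$grid$points_per_dim, "^3 nodes, bounds [",
      x$grid$bounds[1], ", ", x$grid$bounds[2], "])\n", sep = "")
  est <- rbind(estimate = x$point_estimates, `posterior sd` = x$posterior_sds)
  print(round(est, 4))
  cat("log evidence:", round(x$log_evidence, 2),
      " max LL:", round(x$ll_max, 2), "\n")
  invisible(x)
}

#' Predictive accuracy of a fitted policy
#'
#' Fraction of trials on which the option with the higher model choice
#' probability is the observed choice; trials where the model is exactly
#' indifferent (0.5) count one half.
#'
#' @param record A `choice_record`.
#' @param trace A `choice_policy_trace` computed at the fitted parameters.
#' @return A fraction in [0, 1].
#' @export
predictive_accuracy <- function(record, trace) {
  if (nrow(record) != nrow(trace)) {
    stop("record and trace lengths differ", call. = FALSE)
  }
  pg <- trace$p_green_choice
  chose_green <- normalize_color(record$choice) == "G"
  score <- ifelse(pg == 0.5, 0.5, (pg > 0.5) == chose_green)
  mean(score)
}

information_criteria <- function(ll, n_params, n_trials) {
  list(ll = ll, n_params = n_params, n_trials = n_trials,
       bic = n_params * log(n_trials) - 2 * ll,
       aic = 2 * n_params - 2 * ll)
}

#' Compare the Bayesian-learner and Rescorla-Wagner choice models
#'
#' Fits the 3-parameter model on beliefs from the volatility-adaptive tracker
#' and the 5-parameter alternative (same choice model over fixed-rate RW
#' beliefs, with free social and reward learning rates), then compares them
#' by BIC and AIC computed from each model's maximum grid log-likelihood.
#' The default `rw_method = "profile"` grids the two learning rates coarsely
#' and reuses the fast 3-D inner grid at each rate pair; `"full"` uses a
#' denser rate grid.
#'
#' @param record A `choice_record`.
#' @param beliefs_reward,beliefs_social Bayesian-tracker trajectories for the
#'   record's schedule (computed once upstream; choice-independent).
#' @param grid [fit_grid()] for the shared (gamma_social, gamma_reward, beta)
#'   dimensions; default 20 points/dim for desk-scale comparison runs.
#' @param alpha_grid Learning-rate values profiled over for the RW model.
#' @param rw_method `"profile"` (default) or `"full"` (denser
#'   `alpha_points`-point rate grid).
#' @param alpha_points Rate-grid size in `"full"` mode (default 20).
#' @param prob_floor Likelihood floor.
#' @return An object of class `model_comparison`: per-model `ll`, `n_params`,
#'   `bic`, `aic`, `estimates`; `preferred_by_bic`, `preferred_by_aic`.
#' @export
compare_models <- function(record, beliefs_reward, beliefs_social,
                           grid = fit_grid(20),
                           alpha_grid = exp(seq(log(0.02), log(1),
                                                length.out = 6)),
                           rw_method = c("profile", "full"),
                           alpha_points = 20,
                           prob_floor = 1e-9) {
  rw_method <- match.arg(rw_method)
  n_trials <- nrow(record)
  oc <- extract_outcomes(record)

  ll_b <- ll_surface(record, beliefs_reward, beliefs_social,
                     grid$values, grid$values, prob_floor)
  ib <- arrayInd(which.max(ll_b), dim(ll_b))
  bayes <- information_criteria(max(ll_b), 3L, n_trials)
  bayes$estimates <- c(gamma_social = grid$values[ib[1]],
                       gamma_reward = grid$values[ib[2]],
                       beta = grid$values[ib[3]])

  if (rw_method == "full") {
    alpha_grid <- exp(seq(log(0.01), log(1), length.out = alpha_points))
  }
  best <- list(ll = -Inf)
  for (as_ in alpha_grid) {
    bs <- track_rw(oc$advice_outcomes, as_)
    for (ar in alpha_grid) {
      br <- track_rw(oc$reward_outcomes, ar)
      ll_rw <- ll_surface(record, br, bs, grid$values, grid$values,
                          prob_floor)
      m <- max(ll_rw)
      if (m > best$ll) {
        ii <- arrayInd(which.max(ll_rw), dim(ll_rw))
        best <- list(ll = m,
                     estimates = c(gamma_social = grid$values[ii[1]],
                                   gamma_reward = grid$values[ii[2]],
                                   beta = grid$values[ii[3]],
                                   alpha_social = as_,
                                   alpha_reward = ar))
      }
    }
  }
  rw <- information_criteria(best$ll, 5L, n_trials)
  rw$estimates <- best$estimates

  structure(list(bayes_volatility = bayes,
                 rw_fixed = rw,
                 preferred_by_bic = if (bayes$bic <= rw$bic)
                   "bayes_volatility" else "rw_fixed",
                 preferred_by_aic = if (bayes$aic <= rw$aic)
                   "bayes_volatility" else "rw_fixed",
                 n_trials = n_trials),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- data.frame(
    model = c("bayes_volatility", "rw_fixed"),
    n_params = c(x$bayes_volatility$n_params, x$rw_fixed$n_params),
    ll = c(x$bayes_volatility$ll, x$rw_fixed$ll),
    BIC = c(x$bayes_volatility$bic, x$rw_fixed$bic),
    AIC = c(x$bayes_volatility$aic, x$rw_fixed$aic))
  print(tab, row.names = FALSE)
  cat("preferred by BIC:", x$preferred_by_bic,
      "| by AIC:", x$preferred_by_aic, "\n")
  invisible(x)
}
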