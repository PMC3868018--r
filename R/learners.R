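#' Grid for the volatility-adaptive Bayesian probability tracker
#'
#' The tracker maintains a joint distribution over three latents: the outcome
#' probability `r` (in (0,1)), its log-volatility `v` (how fast `r` drifts),
#' and the log-volatility-of-volatility `k` (how fast `v` drifts; static per
#' run). Defaults: 30 points per dimension, `r` equispaced on [0.01, 0.99],
#' `v` on [-11, -2], `k` on [-8, 2] (log scale) — a resolution/runtime
#' trade-off in line with published reimplementations of this tracker family.
#'
#' @param r_points,v_points,k_points Grid sizes (each >= 5).
#' @param r_bounds,v_bounds,k_bounds Numeric ranges; `r_bounds` must lie
#'   strictly inside (0, 1).
#' @return An object of class `learner_grid` with numeric grids `r`, `v`, `k`.
#' @export
learner_grid <- function(r_points = 30, v_points = 30, k_points = 30,
                         r_bounds = c(0.01, 0.99),
                         v_bounds = c(-11, -2),
                         k_bounds = c(-8, 2)) {
  if (min(r_points, v_points, k_points) < 5) {
    stop("all grid point counts must be >= 5", call. = FALSE)
  }
  if (r_bounds[1] <= 0 || r_bounds[2] >= 1 || r_bounds[1] >= r_bounds[2]) {
    stop("r_bounds must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!all(is.finite(c(v_bounds, k_bounds)))) {
    stop("v_bounds and k_bounds must be finite", call. = FALSE)
  }
  structure(list(r = seq(r_bounds[1], r_bounds[2], length.out = r_points),
                 v = seq(v_bounds[1], v_bounds[2], length.out = v_points),
                 k = seq(k_bounds[1], k_bounds[2], length.out = k_points)),
            class = "learner_grid")
}

# Discretized transition kernels.
#  - r-step: beta kernel with mean r and concentration exp(-v); dispersion of
#    the latent probability grows with exp(v), so high volatility means fast
#    forgetting. Columns normalized over the r grid.
#  - v-step: Gaussian random walk with sd exp(k), normalized over the v grid.
# k itself is static (no transition).
transition_kernels <- function(grid) {
  R <- length(grid$r); V <- length(grid$v); K <- length(grid$k)
  Tr <- array(0, c(R, R, V))
  for (vi in seq_len(V)) {
    conc <- exp(-grid$v[vi])
    for (j in seq_len(R)) {
      d <- stats::dbeta(grid$r, conc * grid$r[j], conc * (1 - grid$r[j]))
      s <- sum(d)
      if (!is.finite(s) || s <= 0) {
        stop("degenerate r-transition kernel at v = ", grid$v[vi],
             call. = FALSE)
      }
      Tr[, j, vi] <- d / s
    }
  }
  Tv <- array(0, c(V, V, K))
  for (ki in seq_len(K)) {
    sd_v <- exp(grid$k[ki])
    for (j in seq_len(V)) {
      d <- stats::dnorm(grid$v, grid$v[j], sd_v)
      s <- sum(d)
      if (!is.finite(s) || s <= 0) {
        stop("degenerate v-transition kernel at k = ", grid$k[ki],
             call. = FALSE)
      }
      Tv[, j, ki] <- d / s
    }
  }
  list(Tr = Tr, Tv = Tv)
}

new_belief_trajectory <- function(estimate, spread, learner) {
  out <- data.frame(trial = seq_along(estimate),
                    estimate = estimate,
                    spread = spread,
                    learner = learner,
                    stringsAsFactors = FALSE)
  class(out) <- c("belief_trajectory", "data.frame")
  out
}

#' Volatility-adaptive Bayesian probability tracker
#'
#' Sequential grid filter over the joint latent `(r, v, k)`. Each trial it
#' (1) propagates `v` through a Gaussian random walk with dispersion `exp(k)`
#' and `r` through a mean-preserving beta transition whose dispersion grows
#' with `exp(v)`; (2) multiplies by the Bernoulli likelihood of the observed
#' outcome; (3) renormalizes. Because volatility is inferred jointly with the
#' probability, the effective learning rate rises in unstable stretches of
#' the outcome sequence and falls in stable ones — the defining feature of
#' this learner.
#'
#' The reported `estimate` for trial i is the *predictive* mean of `r`,
#' computed after propagation but before trial i's outcome is seen, so a
#' choice made on trial i never sees trial i's feedback. `spread` is the SD
#' of the same predictive marginal. Under the symmetric uniform prior the
#' first estimate is exactly 0.5.
#'
#' @param outcomes 0/1 outcome sequence.
#' @param grid A [learner_grid()].
#' @return A `belief_trajectory` data.frame (`trial`, `estimate`, `spread`,
#'   `learner`), with attribute `next_estimate`: the predictive mean for the
#'   trial after the last observed one.
#' @export
track_bayes <- function(outcomes, grid = learner_grid()) {
  outcomes <- assert_binary(outcomes)
  if (!inherits(grid, "learner_grid")) {
    stop("grid must be a learner_grid", call. = FALSE)
  }
  kern <- transition_kernels(grid)
  R <- length(grid$r); V <- length(grid$v); K <- length(grid$k)
  n <- length(outcomes)
  joint <- array(1 / (R * V * K), c(R, V, K))
  TvT <- lapply(seq_len(K), function(ki) t(kern$Tv[, , ki]))
  est <- numeric(n)
  spread <- numeric(n)

  propagate <- function(joint) {
    for (ki in seq_len(K)) joint[, , ki] <- joint[, , ki] %*% TvT[[ki]]
    for (vi in seq_len(V)) joint[, vi, ] <- kern$Tr[, , vi] %*% joint[, vi, ]
    joint
  }
  r_mean_sd <- function(joint) {
    m <- rowSums(joint)
    m <- m / sum(m)
    mu <- sum(grid$r * m)
    c(mu, sqrt(max(0, sum(grid$r^2 * m) - mu^2)))
  }

  for (i in seq_len(n)) {
    joint <- propagate(joint)
    ms <- r_mean_sd(joint)
    est[i] <- ms[1]
    spread[i] <- ms[2]
    lik <- if (outcomes[i] == 1L) grid$r else 1 - grid$r
    joint <- joint * lik   # recycles along the r (first) dimension
    s <- sum(joint)
    if (!is.finite(s) || s <= 0) {
      stop("posterior mass vanished at trial ", i, call. = FALSE)
    }
    joint <- joint / s
  }
  out <- new_belief_trajectory(est, spread, "bayes_volatility")
  attr(out, "next_estimate") <- r_mean_sd(propagate(joint))[1]
  out
}

#' Fixed-learning-rate Rescorla-Wagner tracker
#'
#' Delta-rule point tracker: `estimate[i+1] = estimate[i] +
#' alpha * (outcome[i] - estimate[i])`, started at `init`. The reported
#' estimates are predictive (trial i's estimate precedes trial i's outcome).
#' `spread` is 0 by convention (point estimate, no posterior).
#'
#' @param outcomes 0/1 outcome sequence.
#' @param alpha Learning rate in [0, 1].
#' @param init Initial estimate (default 0.5).
#' @return A `belief_trajectory` data.frame with attribute `next_estimate`.
#' @export
track_rw <- function(outcomes, alpha, init = 0.5) {
  outcomes <- assert_binary(outcomes)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  if (init <= 0 || init >= 1) stop("init must be in (0, 1)", call. = FALSE)
  n <- length(outcomes)
  est <- numeric(n + 1)
  est[1] <- init
  for (i in seq_len(n)) {
    est[i + 1] <- est[i] + alpha * (outcomes[i] - est[i])
  }
  out <- new_belief_trajectory(est[seq_len(n)], rep(0, n), "rw_fixed")
  attr(out, "next_estimate") <- est[n + 1]
  out
}

#' Per-trial effective learning rate of a tracker
#'
#' `gain[i] = (estimate[i+1] - estimate[i]) / (outcome[i] - estimate[i])`,
#' i.e. the fraction of the prediction error absorbed into the next estimate.
#' For the Rescorla-Wagner tracker this is `alpha` on every trial; for the
#' Bayesian tracker it varies with inferred volatility. Undefined (NA) where
#' the outcome equals the estimate exactly.
#'
#' @param trajectory A `belief_trajectory` produced by [track_bayes()] or
#'   [track_rw()] on exactly these `outcomes`.
#' @param outcomes The 0/1 sequence the trajectory was computed from.
#' @return Numeric vector of length `length(outcomes)`.
#' @export
adaptive_gain <- function(trajectory, outcomes) {
  outcomes <- assert_binary(outcomes)
  n <- length(outcomes)
  if (nrow(trajectory) != n) {
    stop("trajectory length does not match outcomes", call. = FALSE)
  }
  nxt <- attr(trajectory, "next_estimate")
  if (is.null(nxt)) {
    stop("trajectory lacks the next_estimate attribute; recompute it with ",
         "track_bayes() or track_rw()", call. = FALSE)
  }
  e <- c(trajectory$estimate, nxt)
  denom <- outcomes - e[seq_len(n)]
  gain <- (e[-1] - e[seq_len(n)]) / denom
  gain[abs(denom) < 1e-12] <- NA_real_
  gain
}
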