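# Independent brute-force oracles. These deliberately share no code with the
# package: literal transcriptions of the model equations and of the full-joint
# filter, evaluated the slow way.

oracle_subjective <- function(p, gamma) {
  1 / (1 + exp(-gamma * (p - 0.5)))
}

# Explicit enumeration of the four joint configurations
# (advice truthful x green correct), normalized by the total probability of
# the observed advice color.
oracle_combine <- function(ps, pg, advice) {
  if (advice == "G") {
    # advice green: truthful & green correct, or lying & blue correct
    p_green_and_advice <- ps * pg
    p_blue_and_advice <- (1 - ps) * (1 - pg)
  } else {
    # advice blue: lying & green correct, or truthful & blue correct
    p_green_and_advice <- (1 - ps) * pg
    p_blue_and_advice <- ps * (1 - pg)
  }
  p_green_and_advice / (p_green_and_advice + p_blue_and_advice)
}

oracle_expected_values <- function(q, rg, rb) {
  c(q * rg, (1 - q) * rb)
}

oracle_softmax <- function(vg, vb, beta) {
  1 / (1 + exp(-beta * (vg - vb)))
}

# Straight-line per-trial recomputation of the whole policy (no shared code).
oracle_trace <- function(gs, gr, beta, schedule, est_reward, est_social) {
  n <- nrow(schedule)
  ps_v <- pg_v <- q_v <- vg_v <- vb_v <- pc_v <- numeric(n)
  for (i in seq_len(n)) {
    ps <- oracle_subjective(est_social[i], gs)
    pg <- oracle_subjective(est_reward[i], gr)
    q <- oracle_combine(ps, pg, schedule$advice[i])
    vg <- q * schedule$r_green[i]
    vb <- (1 - q) * schedule$r_blue[i]
    ps_v[i] <- ps; pg_v[i] <- pg; q_v[i] <- q
    vg_v[i] <- vg; vb_v[i] <- vb
    pc_v[i] <- oracle_softmax(vg, vb, beta)
  }
  data.frame(p_hat_social = ps_v, p_hat_green = pg_v, q_hat = q_v,
             v_green = vg_v, v_blue = vb_v, p_green_choice = pc_v)
}

oracle_ll <- function(gs, gr, beta, record, est_reward, est_social,
                      floor = 1e-9) {
  tr <- oracle_trace(gs, gr, beta, record, est_reward, est_social)
  ll <- 0
  for (i in seq_len(nrow(record))) {
    p <- if (record$choice[i] == "G") tr$p_green_choice[i] else
      1 - tr$p_green_choice[i]
    ll <- ll + log(max(p, floor))
  }
  ll
}

# Full-joint brute-force filter: builds the complete (r, v, k) x (r, v, k)
# transition matrix and renormalizes the flattened joint by explicit
# summation every trial. Same kernel definitions as the tracker's contract,
# assembled and applied in a completely different way.
oracle_bayes_filter <- function(outcomes, r, v, k) {
  R <- length(r); V <- length(v); K <- length(k)
  N <- R * V * K
  idx <- function(ri, vi, ki) ri + (vi - 1) * R + (ki - 1) * R * V

  Tr <- array(0, c(R, R, V))
  for (vi in seq_len(V)) for (j in seq_len(R)) {
    d <- dbeta(r, exp(-v[vi]) * r[j], exp(-v[vi]) * (1 - r[j]))
    Tr[, j, vi] <- d / sum(d)
  }
  Tv <- array(0, c(V, V, K))
  for (ki in seq_len(K)) for (j in seq_len(V)) {
    d <- dnorm(v, v[j], exp(k[ki]))
    Tv[, j, ki] <- d / sum(d)
  }
  # one-trial transition: v-step then r-step, k static
  TM <- matrix(0, N, N)
  for (ki in seq_len(K)) {
    for (vi_new in seq_len(V)) for (vi_old in seq_len(V)) {
      pv <- Tv[vi_new, vi_old, ki]
      if (pv == 0) next
      for (ri_new in seq_len(R)) for (ri_old in seq_len(R)) {
        TM[idx(ri_new, vi_new, ki), idx(ri_old, vi_old, ki)] <-
          TM[idx(ri_new, vi_new, ki), idx(ri_old, vi_old, ki)] +
          pv * Tr[ri_new, ri_old, vi_new]
      }
    }
  }
  r_of <- rep(r, times = V * K)

  joint <- rep(1 / N, N)
  n <- length(outcomes)
  est <- numeric(n)
  spread <- numeric(n)
  mass <- numeric(n)
  for (i in seq_len(n)) {
    joint <- as.vector(TM %*% joint)
    mr <- tapply(joint, rep(seq_len(R), times = V * K), sum)
    mr <- mr / sum(mr)
    est[i] <- sum(r * mr)
    spread[i] <- sqrt(max(0, sum(r^2 * mr) - est[i]^2))
    lik <- if (outcomes[i] == 1) r_of else 1 - r_of
    joint <- joint * lik
    joint <- joint / sum(joint)
    mass[i] <- sum(joint)
  }
  list(estimate = est, spread = spread, mass = mass)
}

# Closed-form OLS for the lasso fraction-1.0 check.
oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}
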