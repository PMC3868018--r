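---
title: "Information weighting in volatile reward and advice learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information weighting in volatile reward and advice learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the scientific question

`infoweight` implements the complete computational analysis for a two-option
probabilistic decision task with social advice. On each of 290 trials an
agent chooses between a green and a blue option. One color is correct each
trial; the probability that green is correct is piecewise constant with
reversals, so it must be tracked continually. Independently, a partner
recommends one option per trial, and the probability that this advice is
correct also drifts with its own reversals. Reward magnitudes (integer
points, uniform on 1–100) vary independently of both probabilities, so a
rational agent sometimes picks the less likely color for its larger payoff.
The task is full-information: the correct color is revealed every trial
regardless of the choice, which makes belief trajectories functions of the
schedule alone, never of behavior.

The scientific question is not *how fast* an agent learns but *how much* it
uses each learned quantity. Two per-subject weights, $\gamma_{\text{social}}$
and $\gamma_{\text{reward}}$, quantify the influence of the tracked advice
fidelity and reward probability on choice; a softmax temperature
$\beta$ absorbs residual stochasticity. The package simulates cohorts with
known weights, recovers the weights by grid-based Bayesian estimation,
compares learning models, and tests whether trait scores statistically
linked to the weights can be re-identified — a full parameter-recovery and
method-validation loop.

## The volatility-adaptive probability tracker

Both outcome sequences (was green correct; was the advice correct) feed a
Bayesian learner that tracks a Bernoulli rate $r$ whose drift speed is
itself uncertain. The joint latent state is $(r, v, k)$: $r$ the current
outcome probability, $v$ its log-volatility, $k$ the log-volatility of $v$
(static within a run). Per trial the filter

1. propagates $v$ through a Gaussian random walk with SD $e^{k}$ and $r$
   through a mean-preserving beta transition with concentration $e^{-v}$
   (high volatility = fast forgetting),
2. records the predictive mean and SD of $r$ — the estimate a choice made
   that trial can use, before feedback arrives,
3. multiplies by the Bernoulli likelihood of the revealed outcome and
   renormalizes.

The prior is uniform over the joint grid, so the first predictive estimate
is exactly 0.5. The default grid is 30 points per dimension with
$r \in [0.01, 0.99]$, $v \in [-11, -2]$, $k \in [-8, 2]$: the resolution is
a runtime/accuracy trade-off, and widening the $v$ range mostly adds mass
to regimes indistinguishable at 290 trials. The kernel family is one
concrete choice among the tracker's published variants; downstream fitting
consumes only the predictive estimate sequence, so the choice is
encapsulated behind `track_bayes()` and configurable through
`learner_grid()`.

Two properties matter and are enforced by tests: the filter equals a
brute-force full-joint implementation to $10^{-10}$, and on stationary
sequences the estimate converges to the true rate within 0.05 for rates
0.2, 0.5, 0.8. A behavioral signature worth knowing: the effective learning
rate (`adaptive_gain()`) is low in stable stretches and rises after
reversals, but the *speed* advantage over a fixed-rate learner appears only
once the environment has exhibited volatility — after a first reversal
following a long stable phase the tracker is rationally sluggish. The test
suite therefore probes adaptivity at a late reversal of a reversal-rich
sequence, which matches the task's design.

The alternative learner (`track_rw()`) is the fixed-rate delta rule
$\hat r_{i+1} = \hat r_i + \alpha(o_i - \hat r_i)$, with separate rates for
the social and reward sequences when used as a full model.

## The choice model

With predictive estimates $p_{\text{social},i}$ and $p_{\text{green},i}$ in
hand, the model per trial $i$:

$$\hat p = \frac{1}{1 + e^{-\gamma (p - 0.5)}}$$

applied to each source with its own $\gamma$. The transform is centered at
0.5: $\gamma > $ about 4 amplifies departures from indifference,
$\gamma \to 0$ flattens the probability to 0.5 so the source is ignored and
only magnitudes drive choice. Combination is Bayes' rule in odds form; when
the advice is green

$$\hat q = \frac{\hat p_s \hat p_g}{\hat p_s \hat p_g + (1-\hat p_s)(1-\hat p_g)},$$

and when the advice is blue the numerator becomes $(1-\hat p_s)\hat p_g$
with the matching denominator. (The second case is implemented as the
normalizing mirror of the first; a literal transcription of the
non-normalizing printed variant is available behind
`combine_advice(..., as_printed = TRUE)` for audit.) Equivalently
$\operatorname{logit} \hat q = \gamma_r (p_g - 0.5) \pm \gamma_s (p_s - 0.5)$,
which is what the vectorized likelihood code uses; tests pin the equality
to the composed form. Expected values are $V_g = \hat q\, r_g$,
$V_b = (1-\hat q)\, r_b$, and the green-choice probability is the softmax
$\sigma(\beta (V_g - V_b))$.

A useful anchor: reward history 0.3 toward blue, advice fidelity 0.7 with
green advice, equal weights and equal magnitudes cancel to exact
indifference; unequal weights break the tie toward the heavier source.

## Fitting: direct numerical integration

The per-subject log-likelihood sums $\log P(C_i = c_i)$ over trials with a
floor of $10^{-9}$ per trial. All three parameters live on $[0.01, 10]$ and
are evaluated on a 50-point-per-dimension grid uniform in log space; the
prior is uniform over that grid (log-uniform), which the source analysis
implies but does not state. Marginals come from summation, the point
estimate is each marginal's mean in log space (exponentiated — a
median-like, scale-respecting summary; the source does not say which point
summary it used), and the reported posterior SD is on the natural scale
because it is the fitting-reliability measure of interest. Degenerate fits
(likelihood zero everywhere) raise an error rather than returning silently.

Numerical choices: the softmax log-probability uses the signed stable form
$-\log(1+e^{-|z|}) + \min(z, 0)$; evidence uses log-sum-exp; beliefs are
clamped at $10^{-9}$ before odds combination. Grid-refinement stability is
tested at 30 vs 60 points (estimates move under 5%); at 20 points the
marginal means still shift by up to ~8%, which is why pipeline defaults use
30 and the headline fits 50.

Model comparison refits the same choice model over fixed-rate beliefs with
free rates $\alpha_s, \alpha_r$ (5 parameters vs 3) and compares
$\mathrm{BIC} = k \ln n - 2\mathrm{LL}$ and $\mathrm{AIC} = 2k -
2\mathrm{LL}$ at each model's maximum grid log-likelihood, $n$ = number of
choice trials. The default fits the rates by profiling over a coarse
log-spaced 6-point rate grid with the fast 3-D grid inside, because a full
5-D grid at 20 points per dimension is two orders of magnitude slower for
identical conclusions on every record we examined; the full mode remains
available (`rw_method = "full"`).

## Synthetic cohorts and what they do (and do not) emulate

`generate_cohort()` draws a subject-by-trait table from a multivariate
normal matching the published subscale means and SDs (inter-trait
correlation 0 by default for identifiability of the selection test; a 0.3
equicorrelated preset stresses the lasso), then sets each subject's
log-parameters by linear loadings on z-scored traits plus Gaussian noise:
Stress Immunity and Fearlessness load on $\log \gamma_{\text{reward}}$,
Stress Immunity and Social Potency on $\log \gamma_{\text{social}}$, each
at $-0.35$ with noise calibrated so each loaded trait correlates about
$-0.35$ with the log-parameter — deliberately the realistic low-signal
regime. Parameter medians sit near $\gamma_{\text{reward}} = 1.1$,
$\gamma_{\text{social}} = 2.2$, $\beta = 0.5$ to resemble reported fit
magnitudes, and draws are clamped just inside the fitting bounds. Traits
influence choices only through the parameters, so conditional on
$(\gamma, \beta)$ the choices carry no trait information.

What the generator does **not** emulate: item-level questionnaire
structure, the unknown true correlation structure among subscales, human
lapses and response biases (synthetic agents are exactly the fitted model,
which is why simulated predictive accuracy, ~95%, exceeds what real
subjects produce), and the study's true reversal schedule, which was never
published — the default block structure (reward probability alternating
0.8/0.2 in five 55–60-trial blocks; advice fidelity 0.75/0.25 in four
70–75-trial blocks) is a documented guess shaped to the published figure,
not a reconstruction. Passing recovery tests therefore validates the
estimation machinery, not any claim about human parameter values.

## The trait-association stage

Optimal scaling with every variable at numeric level reduces to the
z-score-times-10 transform, so `optimal_scale()` *is* the scaling machinery
(population-SD denominator by default, configurable; Pearson correlations
downstream are affine-invariant). Variable selection solves, for each
shrinkage fraction $f \in \{0, 0.02, \dots, 1\}$, least squares subject to
$\|\beta\|_1 \le f\,\|\beta_{\mathrm{OLS}}\|_1$. The solver is an exact
lasso homotopy (piecewise-linear path in the penalty, with active-set drops),
so constrained solutions at any fraction are exact interpolations between
knots — no iterative tolerance is involved; tests cross-check the knots
against an independent penalized-regression implementation. Model choice
uses the .632 bootstrap (100 samples): $0.368 \times$ apparent error
$+\ 0.632 \times$ out-of-bag error, squared loss, plain (not .632+)
weighting, ties broken toward the smaller fraction; empty out-of-bag draws
are redrawn and counted. Selected traits then get Pearson correlations with
10,000-sample percentile bootstrap CIs, significant iff the CI excludes 0.

Normality checks use the Kolmogorov–Smirnov distance against a normal with
estimated mean/SD. Because the parameters are estimated, the default
p-value applies the Lilliefors correction; the uncorrected asymptotic
p-value (conservative in this situation, and under-powered against
alternatives like the uniform) is available as `method = "asymptotic"`.
The Lilliefors default is what makes the test simultaneously calibrated on
normal samples and powered on uniform ones.

### A known limitation, quantified

On null cohorts (no trait loads on anything, $n = 36$), the selection
procedure returns an empty or near-zero model in only a minority of
replicates. The reason is structural: among 8 independent null traits at
$n = 36$, the largest absolute sample correlation with the parameter is
about 0.3 in expectation, and because in-bag and out-of-bag subjects come
from the *same* cohort, the .632 bootstrap validates that cohort-level
fluke internally. The error-curve dip at small positive shrinkage is real
within the cohort, not estimator noise. Any internal-validation selector
shares this behavior at this sample size; specificity claims from a single
36-subject cohort should therefore lean on the CI-excludes-zero criterion
of the correlation stage, not on selection frequency alone. The loaded
cohorts are unaffected: loaded traits are selected far above every
unloaded trait and their recovered correlations are reliably negative.

## Problem sizes and reproducibility

The validation experiments run at study scale by choice: recovery uses 40
agents at 290 trials on the 50-point fit grid; model comparison 36 agents;
association recovery 20 loaded plus 20 null cohorts of 36 subjects
(association-stage replicates reuse a minimal 4-trial schedule because only
traits and parameters enter that stage); calibration checks use 200
replicates each. Every stochastic stage takes an explicit seed, and
`run_pipeline()` writes a manifest with settings, seeds, and per-file
checksums; identical configurations reproduce byte-identical outputs.

## Module map

| Stage | Functions |
|---|---|
| Task schedules | `schedule_config`, `generate_schedule`, `extract_outcomes` |
| Learners | `learner_grid`, `track_bayes`, `track_rw`, `adaptive_gain` |
| Choice model | `subjective_probability`, `combine_advice`, `expected_values`, `choice_probability`, `policy_trace` |
| Synthetic data | `agent_spec`, `simulate_agent`, `generate_cohort`, `ppi_subscale_stats`, `default_trait_map`, `null_trait_map` |
| Inference | `fit_grid`, `log_likelihood`, `fit_posterior`, `predictive_accuracy`, `compare_models` |
| Traits | `optimal_scale`, `lasso_path`, `select_optimal`, `bootstrap_corr`, `ks_normality`, `associate_traits` |
| I/O and driver | `read_trial_log`, `write_trial_log`, `read_traits_table`, `write_traits_table`, `run_config`, `run_pipeline` |

The numbered scripts under `analysis/` are thin narrative drivers over
these functions: simulate the cohort, fit every subject, compare models,
run both trait associations, each writing its tables under `results/`.
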