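---
title: "Adaptive allocation in dose-response trials: models, designs, and the learned rule"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive allocation in dose-response trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A phase II dose-ranging trial assigns N subjects to K predetermined doses
(here the five-arm grid 0, 2, 4, 6, 8 mg with N = 150) and, at the end,
asks four questions: is there any dose-response at all (power / type-I
error), which of the candidate curve shapes fits best (model selection,
"MS"), what is the minimum effective dose (target-dose accuracy, "TD"), and
how close is the whole estimated curve to the truth (mean absolute error,
"MAE")? Equal allocation is the near-universal default, but it is not
optimal for any one of these objectives. `doserl` implements the full
simulation stack for this setting — scenario generator, MCP-Mod analysis,
model-averaged optimal designs — and a policy-gradient learner that trains a
blockwise adaptive allocation rule to directly optimize whichever metric
the clinical team cares about.

## Response model and scenarios

Responses are Gaussian, `Y ~ N(mu(d), sigma^2)` with `sigma^2 = 4.5`,
homoscedastic across doses. Six mean-curve families are supported: linear,
Emax, sigmoid Emax, quadratic, exponential and flat. Each non-flat scenario
curve is *calibrated*: the scale coefficient is solved so that the maximum
of `mu(d) - mu(0)` over the dose range equals a stated maximum effect
(1.65, or 1.65 scaled by 0.8 / 1.2) exactly. Calibration is kept at full
floating-point precision; the widely quoted 2-3-digit coefficients (e.g.
an Emax numerator of 1.81) are roundings of the calibrated values
(1.8131...), and using the rounded values shifts the implied target doses
by more than their printed precision. The scenario table
(`scenario_table()`) carries 16 scenarios: the three candidate shapes at
three effect sizes each, quadratic and exponential robustness scenarios,
and a flat null.

The clinically relevant effect is `delta = 1.3`. The target dose (minimum
effective dose) is the smallest continuous dose whose effect over placebo
reaches `delta`; it is found by bisection on the ascending branch of the
curve (the quadratic is restricted to `[0, vertex]`), to a bracket width of
1e-12 mg — far tighter than needed for reporting, but cheap, and it lets
finite-difference oracles in the test suite differentiate through the
solver. The TD correctness band is the dose interval whose effects lie
within `delta (1 +/- eta)`, `eta = 0.1`, with a missing or out-of-range
upper end clipped to the top dose.

## The analysis chain (MCP-Mod)

At trial end the per-dose summaries feed a multiple contrast test over the
three candidate models (linear; Emax with ED50 = 0.79; sigmoid Emax with
ED50 = 4, Hill 5 — all calibrated to maximum effect 1.65, prior 1/3 each).
Each candidate's optimal contrast maximizes the noncentrality of its
single-contrast t-test; the max-T statistic is referred to the one-sided
multivariate t distribution with the contrast-induced correlation and
`sum(n) - K` degrees of freedom. We use the multivariate *t* (not a normal
approximation): with 145 degrees of freedom the difference is small but the
t is the exact finite-sample reference for Gaussian data. For up to three
contrasts the integrals are evaluated with deterministic quadrature
(TVPACK); beyond that, quasi-Monte-Carlo integration under a fixed internal
seed, so analyses are reproducible and never perturb the caller's RNG
stream.

Candidate fitting is least squares on the individual responses, using the
group sufficient statistics (the individual-level RSS decomposes as
within-group SS plus an n-weighted between-group term). Placebo response
and scale are linear and profiled out; ED50 is searched on
`[0.001 d_K, 1.5 d_K]` and the Hill exponent on `[0.5, 10]` — bounds that
mirror common dose-finding practice and stabilize the four-parameter
sigmoid fit — via a coarse log-scale profile grid followed by bounded local
refinement. `AIC = n log(RSS/n) + 2 (p + 1)` with one extra parameter for
the residual variance; the minimum-AIC model is selected, ties broken
toward fewer parameters, then input order.

When no candidate passes the test, selection and metric computation are
still performed over all candidates — the evaluation convention, with
significance carried separately for the power metric. A
`significant_only` flag restricts selection to passing models for use as a
primary analysis.

## Optimal design baselines

The D-criterion is the model-averaged, per-parameter-normalized
log-determinant: minimize `-sum_m (p_m / k_m) log det M_m(w)`, where `M_m`
is the (unit-variance) Fisher information of model m under weights `w` and
`k_m` its parameter count. The normalization `p_m / k_m` is what makes
models of different dimension commensurable, and it is the weighting that
reproduces the reference allocation ratios (0.30, 0.20, 0.12, 0.09, 0.29).
The TD-criterion averages the log asymptotic variance of the estimated
target dose, `sum_m p_m log v_m(w)` with `v_m = b' M_m(w)^- b` and `b` the
gradient of the target dose in the model parameters obtained by implicit
differentiation of `mu(d; theta) - mu(0; theta) = delta`; a generalized
inverse (eigendecomposition, 1e-10 relative cutoff) with an estimability
check guards designs under which the target dose is not identified.

Both criteria are minimized over the K-simplex through a softmax
reparameterization with BFGS and 20 seeded random restarts — the dimension
is tiny and the objectives smooth, so restarts are cheap insurance against
local minima. Continuous weights are turned into subject counts by
Pukelsheim-Rieder efficient rounding, which maximizes `min_k n_k / w_k`
over apportionments (verified against exhaustive enumeration in the test
suite). The adaptive variants re-optimize each 10-subject block given the
counts already on the ground, with candidate model probabilities
re-weighted by each model's maximized Gaussian profile likelihood (placebo
response and scale free, shapes fixed, variance profiled out) — a
normalized-likelihood reading of the posterior update, computed in log
space. Blockwise re-optimization warm-starts from the previous block's
solution with a 1e-8 objective tolerance.

## The trial MDP and the learned rule

A trial is an episode: 50 subjects are split equally across the doses, then
B = 10 blocks of 10 subjects are allocated by the rule, then the analysis
runs. The state after each block is the 3K-1 vector of placebo-differences
of the group means, the group standard deviations (n-1 denominator), and
the allocation proportions `n_k / N`. Rewards are terminal only:
indicator rewards for power, MS and TD, and `1 - 2 MAE` for the curve
error (not clipped; a very bad fit can push it slightly below 0). During
training each action assigns the whole block to a single dose — a
variance-reduction device — while at deployment the block's subjects are
drawn i.i.d. from the policy's distribution `pi(k | s)` (or apportioned
deterministically by efficient rounding, as an option).

The policy is a two-hidden-layer ReLU network (256 units by default) with
a K-way softmax head; a critic of the same architecture estimates the
state value. Training is proximal policy optimization: clipped surrogate
(epsilon = 0.2), Adam (3e-4), 10 epochs of minibatch 64 per update, one
update per 1000 simulated trials, discount 1 (fixed horizon, terminal
reward), advantages normalized per update. Training scenarios are drawn
uniformly from the three candidate curves, matching the prior used by the
analysis. All training randomness flows from a single seed; with a fixed
seed the parameter trajectory is exactly reproducible.

Because an adaptive rule changes the null distribution of the trial's
minimum adjusted p-value, `adjust_significance()` recalibrates the
threshold: it simulates the rule under the flat scenario and returns the
`floor(n alpha)`-th order statistic of the null p-values, the largest
threshold whose null rejection rate does not exceed the target. The
adjustment batch should be independent of the final evaluation batch
(different master seed) to avoid selection bias.

## Reproducibility and random numbers

Each trial derives three independent L'Ecuyer-CMRG substreams from its
master seed (scenario choice, response noise, allocation sampling), so a
record is a pure function of (rule, scenario, config, seed) and rules can
be compared under common random numbers. Per-scenario evaluation seeds
derive from the master seed plus the scenario id.

## Problem sizes used by the tests

The packaged test-suite runs the pieces at sizes chosen to give clear
verdicts quickly: geometry and design reproduction are exact or
deterministic and run in seconds; test calibration uses 2000 flat-scenario
trials (Monte-Carlo standard error about 0.0035 on a 0.025 rate);
policy-gradient convergence is demonstrated on a degenerate
single-good-dose task (final policy entropy below 0.3 nats); and the
learned rules are compared with equal allocation on the candidate scenarios
at 5000 training episodes and 400 evaluation trials per scenario as a
non-inferiority check under common random numbers. Sharper contrasts
between the learned and classical rules — the regime where the adaptive
rule's advantage becomes statistically unambiguous — require orders of
magnitude more training (the reference setting is one million episodes)
and are left to users with the corresponding compute budget; the trainer
itself scales to that setting unchanged.

## What the generator does and does not emulate

The simulator reproduces the stylized phase II setting: Gaussian,
homoscedastic noise with known variance, instantaneous responses, no
dropout, no covariates, a fixed dose grid with placebo. Passing tests
therefore demonstrate correctness of the machinery and the learning signal
under these assumptions — not robustness to heteroscedasticity, delayed or
missing outcomes, or model families far outside the candidate set (the
exponential scenarios in the table exist precisely to probe that last gap,
and an option to include the exponential family among the training
scenarios is provided via a custom candidate set). Safety- or
ethics-driven allocation constraints are out of scope; the natural hooks
are a larger equal initial allocation or a penalized reward.

## Known limitations

* The sigmoid Emax fit profiles a 2-D shape box; pathological interim data
  can still pin it at a bound (flagged via `converged`).
* The Hill-exponent gradient is undefined at `d = 0`; the implementation
  uses the (correct) zero limit, but designs concentrated entirely near
  placebo make the 4-parameter information matrix nearly singular, which
  the criteria signal as `+Inf`.
* PPO hyperparameters are the common defaults, recorded in every trained
  policy object; no tuning beyond the learning rate used in the fast
  demonstration tasks was attempted.
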