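# doserl

Adaptive subject allocation for phase II dose-response trials, learned by
deep reinforcement learning — together with the complete classical stack it
is benchmarked against.

## The problem

A dose-ranging trial spreads N subjects over K fixed doses (placebo
included) and ends with an MCP-Mod analysis: a max-T multiple contrast test
for detecting dose-response, AIC selection among candidate curve shapes,
and estimation of the minimum effective dose (MED). Equal allocation is the
default in practice, but it is not the allocation that maximizes power,
model-selection accuracy (MS), target-dose accuracy (TD), or curve accuracy
(mean absolute error, MAE). Classical optimal designs fix this
asymptotically:

* **D-optimal** — minimize `-Σ_m (p_m / k_m) log det M_m(w)`, the
  model-averaged, per-parameter-normalized information determinant;
* **TD-optimal** — minimize `Σ_m p_m log v_m(w)`, the model-averaged log
  asymptotic variance of the estimated MED, with `v_m = b' M_m(w)⁻ b` and
  `b = ∂d_targ/∂θ` by implicit differentiation.

`doserl` implements these (with Pukelsheim–Rieder efficient rounding and
blockwise adaptive variants), and additionally learns an *adaptive rule*
`π(k | s)` directly: the trial is treated as a Markov decision process
whose state `s` holds the placebo-differences of the dose means, the group
standard deviations and the allocation proportions, whose actions allocate
the next block of subjects, and whose terminal reward is the metric the
team wants optimized (`1{detected}`, `1{right model}`, `1{MED in band}`, or
`1 − 2·MAE`). The rule is a two-hidden-layer ReLU network trained with
proximal policy optimization (PPO) over simulated trials.

## Worked example

```r
library(doserl)

tab <- scenario_table()           # 16 calibrated scenarios
head(tab[, c("id","family","max_effect","d_targ","lower","upper")], 4)
#>   id family max_effect d_targ lower upper
#> 1  1 linear       1.65   6.30  5.67  6.93
#> 2  2 linear       1.32   7.88  7.09  8.00
#> 3  3 linear       1.98   5.25  4.73  5.78
#> 4  4   emax       1.65   2.00  1.44  2.95

cand <- candidate_set()           # linear / Emax / sigEmax, prior 1/3 each
opt  <- optimize_design(cand, "D")
round(opt$w, 4)                   # model-averaged D-optimal weights
#> [1] 0.2973 0.1999 0.1158 0.0921 0.2947
efficient_round(opt$w, 150)       # Pukelsheim-Rieder apportionment
#> [1] 44 30 18 14 44

sc  <- get_scenario(tab, 4)       # Emax truth, MED = 2.00 mg
rec <- run_trial(rule_doptimal(), sc, trial_config(), seed = 1)
round(rec$metrics, 4)
#>  power     MS     TD    MAE
#> 1.0000 1.0000 0.0000 0.1762
```

The scenario table shows, per scenario, the continuous MED (`d_targ`, the
smallest dose with effect ≥ δ = 1.3 over placebo) and the dose band whose
effects lie within δ(1 ± 0.1) — the TD correctness criterion. The trial
record reports all four metrics for one simulated 150-subject trial:
dose-response was detected, the right family was selected, the estimated
MED fell outside the band (TD = 0), and the fitted curve missed the truth
by 0.18 response units on average across the active doses.

Training and deploying a learned rule:

```r
cfg <- trial_config(metric = "MAE")
pol <- train_policy(cfg, episodes = 100000, seed = 1)   # PPO
res <- evaluate_rule(rule_rl(pol), scenario_ids = 1:16, n_sims = 2000, config = cfg)
adj <- adjust_significance(rule_rl(pol), cfg)           # type-I recalibration
```

See the vignette (`vignettes/adaptive-allocation.Rmd`) for the models,
criteria, numerical choices and their rationale.

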