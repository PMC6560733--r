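# wahr: the weighted all-cause hazard ratio for composite endpoints

Clinical trials often combine several event types of different clinical
relevance — death, myocardial infarction, hospitalization — into one
composite time-to-first-event endpoint. The standard effect measure, the
all-cause hazard ratio, treats every event type alike, so a frequent but
mild component can mask a rare but fatal one. The **weighted all-cause
hazard ratio** (WHR) addresses this by attaching non-negative relevance
weights \(w_{EP_j}\) to the cause-specific hazards:

```
lambda_CE^w(t) = sum_j w_{EP_j} * lambda_{EP_j}(t)

theta_CE^w(t) = lambda_CE^{I,w}(t) / lambda_CE^{C,w}(t)
```

where `I`/`C` index the intervention and control arms. With all weights
equal to 1 the WHR is the ordinary all-cause hazard ratio, so it is a
strict generalization of the standard analysis.

`wahr` is aimed at biostatisticians planning or analysing trials with
composite endpoints, and at methodologists benchmarking weighted effect
measures. It provides:

* **Point estimators** at an evaluation time `t = tau`:
  * *non-parametric*: the ratio of weighted sums of cause-specific
    Nelson-Aalen cumulative hazards,
    `sum_j w_j Lhat^I_j(t) / sum_j w_j Lhat^C_j(t)`;
  * *parametric*: per cause a two-group Weibull proportional-hazards model
    (shared shape, group-specific scales) fitted by maximum likelihood, the
    fitted hazards plugged into the weighted ratio.
* **Tests** of the one-sided null `H0: theta_CE^w >= 1`:
  * the standard log-rank test;
  * the *weight-based* log-rank test, which weights observed and expected
    event counts per event **type** (not per time point) and uses
    `w_j^2`-weighted hypergeometric variances;
  * a group-label **permutation test** for either estimator, which also
    yields permutation standard errors and normal-theory confidence
    intervals on the log scale.
* **A trial simulator**: cause-specific Weibull / Gompertz-Makeham hazards,
  latent event times drawn by inverse-cumulative-hazard sampling,
  administrative censoring at `tau`, and a registry of ten benchmark
  scenarios (`list_scenarios()`) spanning situations where the estimators'
  assumptions hold or fail.
* **Performance machinery**: bias, standardized bias, root-MSE, relative
  efficiency, confidence-interval coverage and empirical power over
  simulation replicates (`run_study()`, `study_table2()`, `study_table3()`).
* **Weight-choice guidance**: `severity_to_weights()` turns severity
  equivalences ("5 hospitalizations are as harmful as 1 death") into a
  weight scheme, and `weight_scheme_curves()` tabulates the implied
  weighted event-time distributions for visual comparison.

## Worked example

Simulate a 200-patient trial from benchmark scenario 1 (constant hazards
0.24 vs 0.4 for the severe component EP1, linearly increasing hazards
0.24t vs 0.8t for the mild component EP2), down-weight the mild component
to 0.1, and estimate and test the weighted effect at `tau = 1`:

```r
library(wahr)

d <- simulate_trial("scenario_1", n_per_group = 100, tau = 1, seed = 8)
d
#> <trial_dataset> 200 subjects (I: 100, C: 100), k = 2 event types, tau = 1
#>   censored: 114  events per type: 48, 38

estimate_whr(d, weights = c(1, 0.1))
#> <whr_estimate> non-parametric (Nelson-Aalen) weighted all-cause hazard ratio at t = 1
#>   weights: 1.0, 0.1
#>   estimate: 0.5641   log estimate: -0.5725

estimate_whr(d, weights = c(1, 0.1), method = "parametric")
#> <whr_estimate> parametric (Weibull) weighted all-cause hazard ratio at t = 1
#>   weights: 1.0, 0.1
#>   estimate: 0.5673   log estimate: -0.5668

weight_based_logrank_test(d, weights = c(1, 0.1))
#> <whr_test> weight-based log-rank test (one-sided alpha = 0.025)
#>   statistic: -2.0271   p-value: 0.02133   reject H0: TRUE

permutation_test(d, weights = c(1, 0.1), method = "parametric",
                 n_perm = 1000, seed = 1)
#> <whr_test> permutation test (one-sided alpha = 0.025)
#>   statistic: -0.5668   p-value: 0.01499   reject H0: TRUE
#>   permutation SE (log scale): 0.2516   95% CI: [-1.0599, -0.0738]
```

Both estimators put the weighted hazard ratio near 0.57 (the intervention
roughly halves the weighted event rate; the true value in this scenario is
`exp(-0.598) = 0.55`), and both tests reject the one-sided null at
`alpha = 0.025`. The permutation interval `[-1.06, -0.07]` on the log scale
excludes 0.

A full Monte-Carlo study of a scenario, with the summary tables of a
simulation report:

```r
study <- run_study("scenario_1", weights = c(1, 0.1), tau = 1,
                   reps = 200, n_perm = 200, seed = 1)
study_table2(study)   # true/estimated effects, event counts, power
study_table3(study)   # bias, rMSE, relative efficiency, coverage
```

## Command-line interface

A thin wrapper over the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "wahr.R", package = "wahr"))')" \
    estimate --data trial.csv --k 2 --tau 2 --weights 1,0.1
```

Subcommands: `estimate`, `test`, `simulate` (with a `--quick` scaled-down
profile), `weights-curves`, `list-scenarios`.

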