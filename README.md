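# pswvar

Asymptotic versus bootstrap variance estimation for propensity-score
weighting, evaluated by Monte Carlo simulation.

## The problem

Observational comparisons of a binary treatment are often analyzed with
propensity-score weights. With `e(x)` the propensity score, the package
implements the four standard weight families —

| family | treated weight | control weight | target population |
|--------|----------------|----------------|-------------------|
| ATE    | `1/e`          | `1/(1-e)`      | whole population |
| ATT    | `1`            | `e/(1-e)`      | the treated |
| MW     | `min(e,1-e)/e` | `min(e,1-e)/(1-e)` | equipoise (matching weights) |
| OW     | `1-e`          | `e`            | overlap population |

— and, for each, Hájek-weighted estimates of the difference in means
(continuous outcomes) and of the risk difference and log relative risk
(binary outcomes). Two standard errors are computed for every estimate:

* the **M-estimation sandwich**, from the stacked estimating equations of
  the logistic propensity model and the two weighted means,
  `Var = A⁻¹ B A⁻ᵀ / n`, whose bread matrix carries the analytic
  derivative of the weights through `e(x; β)` and therefore accounts for
  the estimation of the propensity score; and
* the **bootstrap** SE: the SD of the estimate across 200 resamples, with
  the propensity model (and any trimming rule) re-estimated in every
  resample.

Whether the closed-form sandwich is adequate — or the bootstrap is worth
its cost — depends on sample size, treatment prevalence, and weight
family. The package's simulation engine measures this on a calibrated
synthetic super-population (1,000,000 subjects, ten correlated covariates,
calibrated logistic treatment selection with c-statistic ≈ 0.80, linear
and logistic outcome models with R² = 0.25 in controls, control-arm risk
0.2 and average risk difference −0.02), reporting per scenario the **SE
ratio** (mean estimated SE ÷ empirical SD of the estimates; 1 is correct)
and the **empirical coverage** of normal-theory 95% confidence intervals.
Propensity-score trimming is included: fixed thresholds δ and Crump's
sample-optimal threshold, with re-estimation of the propensity score after
trimming. Balance (weighted standardized mean differences), Kish
effective sample size, and a kernel-density overlapping coefficient round
out the diagnostics.

Intended users: biostatisticians and epidemiologists studying (or
teaching) variance estimation for weighted causal effect estimates, and
anyone needing a tested reference implementation of these estimators.

## Worked example

```r
library(pswvar)

pop <- make_super_population(1e5, target_prevalence = 0.3, seed = 1)
pop$calibration$alpha0_treat
#> [1] -1.003418          # intercept calibrated to prevalence 0.3

smp <- draw_sample(pop, 1000, seed = 2)
fit <- fit_propensity(smp$X, smp$Z)
c_statistic(fit$fitted_ps, smp$Z)
#> [1] 0.7829147          # discrimination of the fitted model

w <- compute_weights(fit$fitted_ps, smp$Z, "OW")
balance_report(smp$X, smp$Z, w)
#> max |weighted SMD|: 1.031e-12
#> effective sample size: treated 292.14 control 436.22 total 728.36

sandwich_variance(smp$X, smp$Z, smp$y_cont, fit, "OW", "continuous")$se
#> mean_diff
#> 0.6029437
bootstrap_se(smp, "OW", B = 200, seed = 3)$se
#>  mean_diff  risk_diff     log_rr
#> 0.61384301 0.03036116 0.16348297
```

The overlap weights balance every covariate in the propensity model
exactly (the 1e-12 is floating-point noise), and at n = 1000 the sandwich
and bootstrap SEs of the weighted mean difference agree to within a few
percent — the pattern the simulation study quantifies scenario by
scenario.

A full scenario, at reduced Monte Carlo size:

```r
cfg <- scenario_config(n_sample = 250, target_prevalence = 0.1,
                       n_replicates = 200, n_bootstrap = 200, seed = 1)
res <- run_scenario(cfg)
print(subset(res$summary$metrics, estimand == "mean_diff" & family == "ATE"),
      row.names = FALSE)
#>  family  estimand     method  se_ratio coverage   n
#>     ATE mean_diff asymptotic 0.6101328     0.78 200
#>     ATE mean_diff  bootstrap 0.8915012     0.93 200
```

At n = 250 with 10% treated, the asymptotic ATE standard error
underestimates the true sampling SD badly (and its nominal 95% intervals
cover only ~78% of the time), while the bootstrap is much closer to
correct — the package's headline finding.
`run_grid("main")`, `run_grid("overlap")`, and `run_grid("trimming")`
reproduce the full factorial designs (45, 9, and 54 scenarios).

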