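---
title: "Asymptotic versus bootstrap standard errors for propensity-score weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymptotic versus bootstrap standard errors for propensity-score weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pswvar)
```

## The question

Propensity-score weighting estimates the effect of a binary treatment from
observational data by reweighting treated and control subjects so that
measured covariates are comparable between groups. Given the estimated
propensity score $e(x)$ — the probability of treatment given covariates —
four weight families are in common use, each targeting a different
population:

* **ATE** (inverse probability of treatment) weights, $Z/e + (1-Z)/(1-e)$,
  targeting the average treatment effect in the whole population;
* **ATT** weights, $Z + (1-Z)\,e/(1-e)$, targeting the effect in the
  treated;
* **matching weights** (MW), $\min(e, 1-e)/e$ for treated and
  $\min(e, 1-e)/(1-e)$ for controls, targeting the equipoise population;
* **overlap weights** (OW), $1-e$ for treated and $e$ for controls, which
  balance every covariate in the propensity model *exactly* in any sample.

Effect estimates are Hájek (normalized) weighted contrasts: the difference
in weighted means (continuous outcomes), the weighted risk difference, and
the log of the weighted relative risk (binary outcomes). The package
answers a practical question about their **standard errors**: when is the
closed-form asymptotic (sandwich) estimator adequate, and when should one
bootstrap instead? It does so by Monte Carlo simulation from a calibrated
synthetic super-population, with the two SE estimators judged by the ratio
of the mean estimated SE to the empirical SD of the estimates across
replicates (1 = correct), and by the empirical coverage of normal-theory
95% confidence intervals.

## The two variance estimators

The asymptotic estimator is the empirical sandwich from M-estimation
theory. For each weight family the estimating equations for the logistic
propensity coefficients $\beta$ are stacked with the two weighted-mean
equations,

$$\sum_i w_1(x_i;\beta)\,Z_i\,(Y_i-\mu_1) = 0, \qquad
  \sum_i w_0(x_i;\beta)\,(1-Z_i)\,(Y_i-\mu_0) = 0,$$

and $\widehat{\mathrm{Var}}(\hat\theta) = A^{-1} B A^{-\top}/n$ with
$A = -n^{-1}\sum_i \partial\psi_i/\partial\theta$ and
$B = n^{-1}\sum_i \psi_i\psi_i^\top$. Because the weight functions enter
the mean equations through $e(x;\beta)$, the bread matrix $A$ contains the
analytic derivative of each weight with respect to $\beta$ — this is what
propagates the uncertainty of the estimated propensity score into the SE.
The delta method then maps the $(\mu_1, \mu_0)$ block to each estimand
(gradient $(1,-1)$ for differences, $(1/\mu_1, -1/\mu_0)$ for the log
relative risk). The derivatives are validated in the test suite against
central finite differences of the stacked equations.

The bootstrap estimator draws 200 simple resamples with replacement and
re-runs the *entire* pipeline on each — propensity re-estimation, weight
computation, trimming when configured, point estimation — and takes the SD
of each estimand across resamples. Resampling is unstratified, the default in
standard practice; unstratified resampling also propagates uncertainty in
the treatment prevalence itself. Degenerate resamples (separation, an empty group, a zero-event
group for the log relative risk) are dropped and counted, never imputed.

Confidence intervals are normal-theory, $\hat\phi \pm 1.96\,\widehat{se}$,
with the relative-risk interval built on the log scale.

## The synthetic super-population

`make_super_population()` builds the study conditions: 1,000,000 subjects
with ten standard-normal covariates, equicorrelated at 0.2. Covariates
x1–x5 stay continuous; x6–x10 are dichotomized at the 10th–50th
percentiles of the latent normal (indicator = 1 below the cut), giving
prevalences 10%–50%. Treatment follows a logistic model with log odds
ratios log(1.1), log(1.2), log(1.5), log(1.75), log(2) on x1–x5 and
log(1.25), log(1.5), log(2), log(0.8), log(0.5) on x6–x10; the intercept is
calibrated by bisection so the population prevalence of treatment hits its
target (0.1–0.9). At the main design the propensity model's c-statistic is
about 0.80; multiplying every slope by a scalar `sigma_scale` (0.4–1.6)
moves it between about 0.64 and 0.87, which is how the overlap-sensitivity
design varies the separation of the groups.

The continuous outcome is linear with main effects (2.5, 2, 1.5, 1, 0.5,
2, 1, 5, 4, 3), a uniform treatment effect of 2, and an error variance
calibrated to three times the variance of the covariate linear predictor,
so the covariates explain exactly 25% of the outcome variance among the
untreated. The binary outcome is logistic with log odds ratios (log 2,
log 1.75, log 1.1, log 1.5, log 1.2, log 2, log 1.5, log 1.1, log 1.25,
log 2); its intercept is calibrated so the control-arm prevalence is 0.2,
then the treatment log odds ratio is calibrated so the population average
risk difference is −0.02. An optional sensitivity flag adds
treatment-covariate interactions to both outcome models with coefficients
0.25 times each main effect.

Several choices here were genuinely open and are worth recording:

* **Coefficient lists.** Every one of the ten covariates carries its own
  distinct coefficient in both the treatment and the outcome model
  (treatment: log 2 on x8, log 0.8 on x9, log 0.5 on x10; outcome:
  log 1.1 on x8, log 1.25 on x9, log 2 on x10). The acceptance tests
  verify that the calibrated treatment intercepts under this assignment
  are −2.69, 0.13 and 2.93 at prevalences 0.1, 0.5 and 0.9.
* **Dichotomization.** Cut points are exact normal quantiles, with the
  indicator equal to 1 *below* the percentile; this is the convention
  under which the calibrated intercepts above and the c-statistic of
  0.80 both hold (the upper-tail mirror image misses both).
* **Calibration target functions.** All bisections (bracket ±20,
  tolerance $10^{-4}$ on the target scale, at most 200 iterations) operate
  on expected probabilities, not realized Bernoulli draws, removing one
  layer of Monte Carlo noise from the constants.
* **Potential-outcome coupling.** Both continuous potential outcomes share
  one noise draw, and both binary potential outcomes share one uniform
  draw (comonotone coupling). Marginal means — hence every estimand — are
  unaffected; the choice only pins down individual-level contrasts, and it
  makes the no-interaction continuous effect exactly 2 for every subject.
* **True estimands** are tilting-function averages over the
  super-population with the *true* propensity: $h(x) = 1$ (ATE), $e$
  (ATT), $\min(e, 1-e)$ (MW), $e(1-e)$ (OW), applied to both potential
  outcomes. For the ATT this agrees with directly averaging the contrast
  over treated subjects, up to Monte Carlo error in the realized
  treatment; the tilting form avoids that realization noise.

## Trimming

Fixed-threshold trimming retains the closed interval
$[\delta, 1-\delta]$ of the fitted propensity (subjects strictly outside
are excluded; $\delta = 0$ keeps everyone). Crump's optimal threshold is
the smallest $\alpha$ with
$1/(\alpha(1-\alpha)) = 2\,\mathrm{mean}\{1/(e_i(1-e_i)) : e_i(1-e_i) \ge
\alpha(1-\alpha)\}$; `crump_threshold()` solves this exactly by scanning
the sorted sample values of $e(1-e)$ as candidate cut levels (a grid
search serves as the test-suite oracle). After trimming, the propensity
model is re-fitted on the retained subjects and all weights use the
re-fitted scores; in bootstrap resamples the whole workflow — including
the Crump threshold itself — is recomputed per resample.

## The engine and its metrics

`run_replicate()` draws one sample without replacement, applies the
trimming workflow, fits the propensity model once, and computes all four
weight families × three estimands × two SE methods, coverage indicators
against the scenario's true estimands, and balance/ESS diagnostics.
`run_scenario()` and `run_grid()` orchestrate replicates over the four
study designs (main: 5 sample sizes × 9 prevalences; interactions;
overlap: 9 values of `sigma_scale`; trimming: 9 × 6 including Crump).
Replicate seeds are derived by deterministic Lehmer-style mixing of
(master seed, scenario id, replicate index), so any scenario or replicate
can be reproduced in isolation and summaries are a pure function of the
configuration. Replicate-level failures (e.g. separation at small n) are
flagged and excluded pairwise, with counts reported.

Headline metrics per (family, estimand, method): the **SE ratio**
(mean estimated SE / SD of point estimates; divisor $R-1$) and the
**empirical coverage** of 95% intervals, judged against the
normal-theory significance band
$0.95 \pm 1.96\sqrt{0.95 \cdot 0.05/R}$ — (0.9365, 0.9635) at the study's
full $R = 1000$.

## Problem sizes and what the checks show

The package's own validation runs use a 1,000,000-subject super-population
for every calibration quantity (matching the study design), and reduced
Monte Carlo sizes for the replicated designs: 200 replicates with 200
bootstrap resamples at n = 250, and 200 replicates for the Crump-threshold
medians at n = 1000. At R = 200 the Monte Carlo SD of an SE ratio is
roughly $1/\sqrt{2R} \approx 0.05$ and the coverage band widens to
(0.920, 0.980); conclusions at this replication are qualitative
reproductions of the full-scale patterns: the ATE asymptotic SE
underestimates the sampling SD at small n and extreme prevalence, the
bootstrap is closer to 1 there, and MW/OW variance estimation is accurate
and stable throughout.

The generator emulates the study conditions exactly — equicorrelated
covariates, logistic selection, uniform (or proportionally interacted)
effects. It does not emulate features of real data such as non-logistic
selection, unmeasured confounding, heavy-tailed outcomes, or clustered
sampling; passing tests certify the variance estimators under the stated
model, not robustness beyond it.

## Worked example

```{r example, eval = FALSE}
pop <- make_super_population(1e5, target_prevalence = 0.3, seed = 1)
smp <- draw_sample(pop, 1000, seed = 2)
fit <- fit_propensity(smp$X, smp$Z)
w <- compute_weights(fit$fitted_ps, smp$Z, "OW")
balance_report(smp$X, smp$Z, w)

mu <- weighted_group_means(smp$y_cont, smp$Z, w)
sandwich_variance(smp$X, smp$Z, smp$y_cont, fit, "OW", "continuous")$se
bootstrap_se(smp, "OW", B = 200, seed = 3)$se
```

## Known limitations

* Survival outcomes, multi-category treatments, and percentile bootstrap
  intervals are out of scope.
* The matching-weight derivative is non-differentiable at $e = 0.5$; the
  sandwich uses the lower branch there (a measure-zero event for
  continuous scores).
* The overlapping-coefficient diagnostic integrates kernel densities on a
  fixed [0, 1] grid (Gaussian kernel, Silverman bandwidth, 512 points);
  boundary leakage makes "perfect overlap" read slightly above 0 rather
  than exactly 0.
* `run_grid()` at the full study scale (45 scenarios × 1000 replicates ×
  200 bootstraps) is a multi-day single-core computation, as in the
  original design; the grid runner writes incrementally and resumes so
  long runs can be split.
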