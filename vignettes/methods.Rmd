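---
title: "Methods: comparing meta-analytic and multi-laboratory replication estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing meta-analytic and multi-laboratory replication estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replimeta)
```

## The problem

For a number of psychological phenomena we now have two independent
estimates of the same effect: a random-effects meta-analysis (MA) of the
published literature, and a single large preregistered multi-laboratory
replication (MLR). The two routinely disagree, with the MA estimate the
larger. `replimeta` implements a pipeline for quantifying that
disagreement phenomenon by phenomenon and for asking how much of it
heterogeneity and publication bias could account for. This vignette is
the package's account of the statistical choices inside that pipeline.

All effect sizes are standardized mean differences (Cohen's *d*); all
study tables are assumed sign-harmonized so the hypothesized direction is
positive (`read_study_table()` offers a `direction_flip` column for
datasets coded the other way).

## Random-effects engine

The model is the standard two-level normal one: study estimates
$y_i \sim N(\theta_i, v_i)$ with known sampling variances $v_i$, and
population effects $\theta_i \sim N(\mu, \tau^2)$. Three $\tau^2$
estimators are available:

* **Paule–Mandel (PM)** — the default everywhere. It solves
  $\sum_i w_i^*(y_i - \hat\mu^*)^2 = k - 1$ with
  $w_i^* = 1/(v_i + \tau^2)$, is moment-based without normality of the
  $y_i$ beyond second moments, and is the conventional choice in the
  publication-bias sensitivity-analysis literature this package builds
  on. The sources we re-implement do not name their estimator, so the
  choice is config-switchable precisely to let users probe sensitivity
  to it.
* **DerSimonian–Laird (DL)** — the closed-form moment estimator; cheap
  and familiar, slightly negatively biased with few, unbalanced studies.
* **REML** — maximizer of the restricted likelihood profiled over $\mu$.

Numerics: all estimators truncate at 0. The PM root is bracketed on
$[0, 100]$ SMD² (the bracket is extended tenfold as needed; effects on
the *d* scale cannot plausibly approach it) and solved by `uniroot` to
tolerance $10^{-8}$; REML uses golden-section `optimize` on the same
interval with a boundary check against the profile value at 0, expanding
the interval whenever the optimum lands within $10^{-3}$ of the upper
end. Tests verify both against brute-force oracles (interval bisection
for PM, a two-stage grid search at step $10^{-4}$ for REML) and against
`metafor` as an independent reference.

The pooled mean uses inverse-variance weights $1/(v_i + \hat\tau^2)$.
Intervals are Wald-z by default — the analyses we mirror report plain
95% CIs with no named small-sample correction — with Knapp–Hartung
(`"hksj"`, t on $k-1$ df with rescaled variance) available. A
single-study "meta-analysis" is a legal input because the worst-case
sensitivity analysis below can discard all but one study: the fit passes
through $(y_1, \sqrt{v_1})$ and is flagged `low_k`.

## Calibrated estimates and the proportion statistic

Comparing only the MA and MLR *means* overstates conflict when effects
are heterogeneous: the MLR mean may sit comfortably inside the
distribution of population effects. The raw spread of the $y_i$
overstates that distribution (it adds sampling error to heterogeneity),
so each estimate is shrunk by its empirical-Bayes factor
$\hat\gamma_i = \hat\mu + \frac{\hat\tau^2}{\hat\tau^2 + v_i}(y_i - \hat\mu)$
and the empirical distribution of the $\hat\gamma_i$ serves as the
estimate of the population-effect distribution. The summary statistic is
$\hat P(q)$, the proportion of $\hat\gamma_i$ *at or below* the MLR
estimate $q$. The comparison is deliberately inclusive (≤, "as small as
or smaller"), and $q$ is treated as a fixed known threshold: MLR
standard errors are an order of magnitude smaller than study-level ones,
and propagating them is out of scope.

**Bootstrap interval.** Uncertainty in $\hat P$ comes from a
bias-corrected and accelerated (BCa) bootstrap resampling *studies* with
replacement — the only resampling level study-level data affords — and
refitting, recalibrating and recounting in each replicate with the same
$\tau^2$ estimator. The bias correction is
$z_0 = \Phi^{-1}\big(\big(\#\{t^* < t_0\} + \tfrac12\#\{t^* = t_0\}\big)/B\big)$
— ties are split at half weight because $\hat P$ lives on a grid of
$k+1$ values and exact ties are common — and the acceleration comes from
the leave-one-out jackknife skewness. Degenerate cases are flagged
rather than papered over: if all replicates coincide, if the bootstrap
distribution falls entirely on one side of $t_0$ (infinite $z_0$), or if
$k < 2$, the interval is reported non-estimable (`ci_estimable = FALSE`,
`NA` bounds). A flat jackknife (zero denominator) sets the acceleration
to 0, reducing BCa to the bias-corrected percentile interval. Estimable
bounds are clipped to $[0,1]$. The default 1000 replicates (floor 200)
and a mandatory seed make every interval reproducible; a plain
percentile variant exists for method-comparison studies.

## Publication-bias sensitivity analysis

The selection model: a study is **affirmative** if
$y_i/\sqrt{v_i} > z_{1-\alpha/2}$ with $\alpha = 0.05$ two-sided
(equivalently one-tailed 0.025 in the positive direction) — and
**non-affirmative** otherwise, including significant results in the
wrong direction. Publication favours affirmative studies by a ratio
$\eta \ge 1$ and selects on nothing else. The z (not t) reference is an
assumption; the sources do not state which they used, and for the
study sizes involved the difference is immaterial.

Two corrections follow:

* `corrected_estimate(data, eta)` up-weights each non-affirmative study
  by $\eta$, since published non-affirmative studies are then a random
  sample of the underlying non-affirmative population. $\hat\tau^2$ is
  estimated **once on the full published dataset** and held fixed inside
  the reweighting. This keeps $\eta$'s effect isolated to the mean,
  makes $\eta = 1$ reproduce the naive mean to machine precision, and
  makes the estimator exactly equivalent to the intuition of replicating
  each non-affirmative study $\eta$-fold (a test oracle).
* `worst_case_estimate(data)` is the $\eta \to \infty$ limit: an
  ordinary random-effects meta-analysis of the non-affirmative subset
  only. Being an ordinary meta-analysis of that subset, it re-estimates
  $\tau^2$ on the subset — so it differs from the large-$\eta$ limit of
  the corrected estimate by exactly the $\tau^2$-handling; tests compare
  the two under matched $\tau^2$. With no non-affirmative study the
  analysis is statistically infeasible and is flagged, not thrown.

A caution established by simulation in this package's tests: the worst
case is conservative *even without publication bias*, because
conditioning on non-significance truncates the upper tail of the
estimate distribution. A worst-case estimate far below the naive one is
therefore not, by itself, evidence of bias; the informative comparison
is worst-case versus MLR.

## The synthetic generator

`sim_config()` / `simulate_meta()` generate literatures exactly under
the assumed model: $\theta_i \sim N(\mu, \tau^2)$,
$y_i \sim N(\theta_i, v_i)$ with the two-arm SMD approximation
$v_i \approx 4/n_i$ and $n_i$ uniform on a configured range, then
independent Bernoulli$(1/\eta)$ publication for non-affirmative studies
(affirmative studies always publish), stopping at `k_published`. The
defaults describe a typical psychology literature: $\mu = 0.3$,
$\tau^2 = 0.1$ (mid-range of the heterogeneity observed across real
meta-analyses, roughly 0–0.5 with mean near 0.1), 20 published studies
of 30–150 participants, and an MLR of 5000 participants
($v \approx 4/n$ again). `suite_template()` draws per-phenomenon
parameters ($\mu_j \sim N(0.4, 0.2^2)$, $\tau^2_j \sim U(0, 0.22)$,
10–40 studies) for 15-phenomenon suites; an `mlr_offset` knob shifts the
MLR's true effect away from $\mu_j$ to emulate worlds where the MA/MLR
gap is substantive (context sensitivity, intervention fidelity) rather
than selection — used for testing only, with no claim about mechanism.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: selection on continuous *p*-values or on
estimate size within significance classes, p-hacking, correlated or
clustered studies, non-normal population effects, site-by-method
interactions inside the MLR, and MLR-side bias of any kind. Passing
recovery tests show the estimators are correct *under their assumed
model*, not that real literatures satisfy that model.

## Cross-phenomenon layer

`correlate_estimates()` uses the Fisher z interval
($\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3}$) and the t-test
p-value on $n-2$ df. This method choice is validated against a published
operating point: at $r = 0.72$, $n = 15$ it reproduces the printed
interval $[0.32, 0.90]$ and $p = 0.003$ — to within the rounding of the
reported $r$ itself, since at exactly 0.72 the lower bound computes to
0.329.

`sensitivity_summary()` filters to phenomena where the naive mean
exceeds the MLR estimate *and* the worst case is estimable, then
averages. Two deliberate reporting choices, both surfaced in the output
rather than resolved silently:

* "Worst-case estimates X% as large as naive" is computed as the
  **mean of per-phenomenon ratios** (`mean_ratio`), which is not the
  ratio of the two means; both are reported (`ratio_of_means`).
* The median of $\hat P$ is reported both over all phenomena with a
  defined value (`median_phat`) and over the included set
  (`median_phat_included`), since the population over which such a
  median is taken is a genuine reporting ambiguity.

Exceedance fractions (`prop_worst_exceeds_mlr`, `_null`) use strict `>`
on point estimates, over the included set.

`run_full_comparison()` orchestrates everything and is a pure function
of its inputs and one seed; per-phenomenon bootstrap seeds are derived
from the phenomenon *identifier* (not its position), so every report
statistic is invariant to input ordering and repeat runs are
byte-identical.

## Problem sizes and limitations

The test suite's simulation studies use sizes chosen to make Monte-Carlo
error comfortably smaller than the effects being detected while keeping
the suite quick to run routinely: 500 replicates for unbiasedness of the
naive estimator ($k = 40$), 300 replicates at $k = 60$ for selection-
bias recovery at $\eta = 5$, 200 replicates at $k = 50$ for quantile
recovery of $\hat P$, and 200 simulated meta-analyses ($k = 25$, 200
bootstrap replicates each) for interval coverage, asserted at ≥ 0.85
against the nominal 0.95 to absorb Monte-Carlo and grid effects.

Known limitations: no meta-regression or moderators; no estimation of
$\eta$ from data (by design — the sensitivity analysis brackets bias
instead of estimating it); no selection models beyond the dichotomous
affirmative/non-affirmative one; MLR sampling error ignored in
$\hat P$; inference on corrected estimates is point-estimate-only. The
$\hat P$ statistic is discrete in small meta-analyses ($k+1$ attainable
values), so its bootstrap intervals are conservative and occasionally
non-estimable at small $k$ — reported as such rather than smoothed.
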