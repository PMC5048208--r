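---
title: "Staged likelihood-ratio models: methods and design notes"
author: "lrbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged likelihood-ratio models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrbayes)
```

## The model

`lrbayes` fits and evaluates a staged probabilistic risk model in which a
patient's probability of a binary outcome — the motivating application is
transition from an ultra-high-risk (UHR) state to a first episode of
psychosis within one year — is updated as information accumulates across
assessment stages. The machinery is the odds-ratio form of Bayes' rule.

Every predictor is reduced to a binary call. A continuous predictor is
called positive when its value crosses a threshold in its direction of
abnormality (`value > t` for high-is-risk markers such as PANSS subscale
scores, `value <= t` for low-is-risk markers such as GAF or
erythrocyte-membrane nervonic acid). Each predictor then contributes one of
two multiplicative updates to the running odds:

$$
\mathrm{LR}^+ = \frac{\mathrm{sens}}{1-\mathrm{spec}},\qquad
\mathrm{LR}^- = \frac{1-\mathrm{sens}}{\mathrm{spec}},
$$

applied as

$$
o_{\text{post}} \;=\; \frac{p_0}{1-p_0}\;\prod_{i}\mathrm{LR}_i,\qquad
p_{\text{post}} \;=\; \frac{o_{\text{post}}}{1+o_{\text{post}}},
$$

with $p_0$ the pretest probability. Updates are applied stage by stage
(historical → clinical → biomarker by default), which yields an
interpretable per-case trajectory; because the product commutes, the final
posterior is invariant to stage and within-stage order, and the package
asserts this to machine precision.

**Assumption.** Multiplying per-predictor likelihood ratios is exactly the
naive-Bayes factorization: predictors must be conditionally independent
given the outcome. Correlated predictors (e.g. the four clinical scales)
make the chained posterior over-confident. The synthetic-cohort generator
exposes a `dependence` parameter precisely so that tests and users can
quantify this degradation; the fitting function does nothing to correct it.

## Model construction

`lrbayes()` follows a three-step pipeline:

1. **Screen.** Each candidate predictor's empirical AUROC is tested against
   0.5 with the DeLong variance; candidates with two-sided $p < \alpha$
   (default $\alpha = 0.05$) are retained. The screen is deliberately
   marginal (one predictor at a time): with a pure-noise candidate it
   retains the noise in $\approx\alpha$ of fits, which the test suite
   checks empirically.
2. **Dichotomize.** Retained continuous predictors get the Youden-optimal
   cut $\operatorname{argmax}_t(\mathrm{sens}+\mathrm{spec}-1)$ over the
   observed values; binary predictors are fixed at threshold 1.
3. **Summarise and chain.** Confusion counts at those cuts give
   sensitivity, specificity and the likelihood ratios, which are carried at
   full precision — rounding to two decimals happens only in display
   columns, because a chained model audited against rounded LRs drifts in
   its third significant digit.

The pretest probability defaults to the cohort outcome rate and is
user-overridable: once the LR table is fixed, transporting the model to a
clinic with a different base rate only requires replacing $p_0$.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `alpha` | 0.05 | AUROC-vs-chance retention level; `alpha = 1` disables the screen. |
| `thresholds` | Youden-optimal | Fixed cuts can be supplied per predictor (units of the predictor). |
| `pretest` | cohort outcome rate | Probability in (0,1). |
| `zero_cell` | `"infinite"` | `LR+` at specificity 1 is reported as `Inf` with a flag; `"haldane"` adds 0.5 to all cells. The infinite default is chosen so that reproduction of printed tables is never silently perturbed. |
| `missing` (prediction) | `"exclude"` | Whole-case exclusion of subjects missing any model predictor, mirroring how incomplete cases are handled in small clinical cohorts; `"skip"` treats a missing call as "no update" (LR 1). |
| bootstrap `n_iterations` | 1000 | BCa interval for sensitivity at fixed specificity. |

## Numerical and convention choices

* **ROC cuts.** Operating points are computed at every distinct observed
  value plus infinite endpoints, with the calling inequalities `>` /
  `<=` matching the conventions of printed cutoff tables. The AUROC is the
  tie-corrected Mann–Whitney statistic, computed from summed midranks so
  the arithmetic is exact half-integer arithmetic — the suite checks bit
  identity against exhaustive pair counting.
* **Youden tie-break.** If several cuts attain the maximal J, the one with
  higher sensitivity wins (a missed transition is clinically costlier than
  a false alarm); residual ties go to the threshold closest to the median
  observed value. Degenerate all-positive/all-negative endpoints are
  excluded unless every interior point has $J \le 0$.
* **Test against chance.** $z=(\widehat{A}-0.5)/\widehat{se}_{DeLong}$,
  two-sided. A perfect or constant classifier has zero DeLong variance; the
  p-value is then reported as a limiting value with an explicit warning
  flag. An exact label-permutation test is available for very small
  samples.
* **Sensitivity at fixed specificity.** Per bootstrap replicate the
  operating point with the *smallest attainable specificity at or above*
  the fixed value is used (conservative). Replicates that resample a single
  outcome class are redrawn with a capped retry count and a warning
  counter; a stratified option sidesteps the issue.
* **BCa details.** The bias-correction constant uses the proportion of
  replicates below the point estimate with ties counted half — the
  statistic is a step function, and the half-tie convention keeps the
  correction meaningful; for continuous statistics it coincides with the
  usual count, and the machinery is cross-checked against `boot::boot.ci`
  on a smooth statistic. Quantiles interpolate order statistics on the
  normal scale. When all replicates fall on one side of the estimate the
  BCa correction is undefined and the percentile interval is returned with
  a warning.
* **Infinite odds.** `odds_to_probability(Inf)` is 1; a predictor with
  `LR- = 0` (perfect sensitivity) can legitimately drive a posterior to 0.

## The synthetic-cohort generator

`uhr_cohort_spec()` encodes the reference study conditions: 40 subjects,
28% outcome prevalence, and seven informative predictors in three groups —
any history of drug use (binary; sens 72.73%, spec 72.41%), PANSS positive
(> 14; 81.82/65.52), PANSS negative (> 12; 72.73/68.97), PANSS general
(> 31; 72.73/75.86), GAF (≤ 60; 90.91/51.72), nervonic acid (≤ 0.2902;
90.91/53.57) and total omega-3 (≤ 5.0727; 81.82/67.86).

For a continuous predictor the generator uses equal-SD class-conditional
Gaussians whose means are solved analytically so that the target
sensitivity and specificity hold exactly at the stated threshold:
$\mu_{\text{case}} = t + \sigma\,\Phi^{-1}(\mathrm{sens})$ and
$\mu_{\text{ctrl}} = t - \sigma\,\Phi^{-1}(\mathrm{spec})$ for high-is-risk
markers (mirrored for low-is-risk). This is the minimal model that admits
an analytic mean-solve, which is what makes every downstream stage testable
against closed-form truth. Targets with
$\mathrm{sens}+\mathrm{spec} < 1$ are rejected: they would require a cut
that is not monotone in the stated direction. Binary predictors are
class-conditional Bernoulli draws with positivity rates
$\mathrm{sens}$ (cases) and $1-\mathrm{spec}$ (non-cases).

The within-class SDs in the default spec (4, 4, 8 points for the PANSS
subscales, 10 for GAF, 0.06 and 1.2 for the fatty-acid percentages) are
plausible instrument scales chosen once for realism of the printed values;
every operating characteristic is location-scale invariant, so they fix
units, not difficulty. Optional features, both off by default: an
equicorrelated latent Gaussian factor per class (`dependence`, a copula
oriented so abnormality is positively associated across predictors, leaving
marginals untouched) for probing the conditional-independence assumption,
and missing-completely-at-random cell deletion (`missing_rate`).

Two caveats on what passing tests show. First, one detail of the reference
analysis the generator does *not* emulate: the source data showed unequal
between-group variances for some predictors (largest for PANSS-negative,
-positive and total omega-3), but no usable per-class SD values are
published, so the generator defaults to equal SDs; per-class behaviour can
be approximated by composing two specs if needed. Second, real psychiatric
predictors are mutually correlated in ways no single equicorrelation
parameter captures; green tests on synthetic cohorts validate the
machinery, not the clinical transportability of any particular LR table.

A note on parameter-recovery testing: when target sensitivity ≠
specificity, the planted threshold is intentionally *not* the population
Youden optimum of the generating Gaussians (that optimum is the mid-mean
point). The recovery test therefore compares fitted thresholds to the
analytic optimum, the quantity Youden estimation is consistent for.

## Evaluation tools

`evaluate_posteriors()` computes the ROC over posterior scores, the Youden
probability threshold, sensitivity/specificity at that cut, and
PPV/NPV from the standard prevalence identities. At the published
full-model operating point (sens 72.73%, spec 96.43%, prevalence 28%) the
identities give PPV 88.8% and NPV 90.1%; the source publication prints
88.5%/90.3% by an unstated computation — the package reports the values as
computed and documents the discrepancy rather than forcing agreement. A
related transcription slip in the source's screening table (the
nervonic-acid Youden index printed as 0.5357, duplicating its specificity,
where its sens/spec row implies 0.4448) is likewise documented in the test
suite and excluded from reproduction checks.

`delong_compare()`/`compare_models()` test paired AUROC differences via
placement-value covariance; the suite checks exact agreement with `pROC`
and ~10% agreement with a brute-force jackknife covariance.

## Problem sizes used in the test suite

Simulation sizes were chosen to make Monte-Carlo error comfortably smaller
than the assertion bands: large-sample generator convergence at
$n = 10^5$ (±0.01), calibration at $n = 10^5$, parameter recovery at
$n = 10^4$, the distributional replication of the combined-model ROC table
at 200 cohorts of $n = 40$, type-I error of the screen at 1000 replicates,
and BCa coverage at 500 cohorts of $n = 100$ with 1000 bootstrap
iterations. Coverage is assessed at $n = 100$ rather than 40 because with
~29 controls the attainable specificities form a grid too coarse for a
nominal 95% level to be meaningful; the small-$n$ behaviour asserted
instead is the realistic interval *width* (> 0.3 at $n = 40$, echoing the
wide published interval at $n = 39$).

## Known limitations

* LRs are estimated at data-driven Youden cuts in the same small sample —
  in-sample evaluation is optimistic; the bootstrap tools quantify but do
  not remove this.
* No joint estimation (logistic regression or Gaussian-process
  alternatives are out of scope) and no correction for predictor
  correlation.
* Two outcome classes only; no time-to-event structure.
* Confidence intervals for individual predictor LRs are not provided.
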