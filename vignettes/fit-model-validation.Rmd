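---
title: "Validating FIT-based colorectal cancer risk models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating FIT-based colorectal cancer risk models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In UK primary care, symptomatic patients with a faecal immunochemical test
(FIT) result of at least 10 µg haemoglobin per gram of faeces are referred
for urgent colonic investigation. Only a small fraction of FIT-positive
patients have colorectal cancer (CRC), so multivariable models combining
FIT with age, sex, platelet count (PLT) and mean cell volume (MCV) have
been proposed to reduce referrals without missing cancers. Before such a
model changes care in a new setting, it must be validated there: the local
FIT distribution, testing volume and symptom case-mix all shift the
operating characteristics, and they shift over time.

`fitvalid` implements the full external-validation battery for this
setting, together with a synthetic cohort generator so that every stage of
the pipeline can be exercised and tested without access to patient-level
records.

## The core metric: matched-sensitivity referral reduction

The clinically meaningful question is not "is the c-statistic higher?" but
"at the *same number of cancers detected*, how many fewer (or more)
patients would test positive?". `matched_sensitivity_threshold()` selects
the model risk cutoff capturing the same number of cancers as FIT ≥ 10
µg/g with as few positive tests as possible: among candidate thresholds —
the distinct observed risk values, since any value between two observed
risks classifies identically — it returns the **largest** threshold whose
cancer count equals the FIT rule's count `T*`. `referral_reduction()` then
reports

* `pct_reduction` = (positives(model) − positives(FIT)) / positives(FIT) × 100
  (negative values are reductions in referrals),
* positives per 1000 tests for both rules,
* sensitivities, their difference in percentage points, and the absolute
  number of cancers missed or gained.

Two conventions deserve note:

* **Tied risk scores.** When ties make an exact cancer-count match
  impossible, the largest threshold capturing *at least* `T*` cancers is
  used — the model is never allowed to miss cancers relative to FIT by
  construction — and the relaxation is logged. An `relax = "exact"` mode
  errors instead.
* **Boundary non-cancers.** "As low false positive rate as possible" means
  the matched threshold sheds any non-cancers ranked between the FIT
  cutoff and the lowest-ranked captured cancer. Consequently even a model
  that is an exact monotone transform of FIT can show a small nominal
  reduction unless the lowest FIT-positive value belongs to a cancer; this
  is a property of the metric, not an artefact.

Thresholds are reported on the percent scale (e.g. 0.64%), as referral
thresholds are usually published. `external_threshold_evaluation()`
evaluates such a fixed external threshold, and `prospective_simulation()`
emulates deployment by applying each period's predecessor threshold —
matched thresholds are order statistics and carry substantial selection
noise, which is exactly what that analysis surfaces.

## Discrimination

* `roc_and_cstat()`: ROC by threshold sweep with linear interpolation; the
  c-statistic is computed from mid-ranks (ties count 1/2) which equals the
  trapezoidal area under that curve by construction, making the tie
  convention explicit.
* `pr_curve_davis_goadrich()`: precision–recall corners at distinct
  thresholds, recall ties collapsed to the maximum-precision corner, and
  false positives interpolated linearly on the integer true-positive grid
  between corners — the achievable performance of classifiers mixing two
  operating points. Linear interpolation in PR space would be optimistic;
  this construction is not.
* `average_precision()`: the step-sum estimator
  `Σ (R_k − R_{k−1}) P_k × 100`; it estimates the prevalence (in percent)
  for a random ranking and 100 for a perfect one.
* `test_reduction_curve()`: `(ppv_fit / ppv_model − 1) × 100` across
  achievable sensitivities. The grid is the set of FIT operating points at
  which a new cancer is captured (cancer-valued thresholds), plus the
  conventional threshold 10 µg/g; at each point the model is operated at
  its matched threshold. Evaluating both tests on recall-achieving corners
  makes a monotone-in-FIT model give an identically zero curve, and
  including the conventional threshold makes the curve agree exactly with
  `referral_reduction()` at the matched sensitivity.

## Calibration and recalibration

`calibration_summary()` reports the event rate, mean predicted risk, their
ratio (O/E; above 1 = under-prediction), and the intercept and slope of a
logistic regression of the outcome on the logit of the predictions. The
intercept and slope are estimated **jointly** — the summary describes one
fitted recalibration line — with `fixed_slope = TRUE` available for the
intercept-given-slope-1 variant. Probabilities are clipped to
`[1e-10, 1 − 1e-10]` before the logit.

`lowess_calibration_curve()` smooths the binary outcome on the prediction
with `stats::lowess` and span `frac = 0.3` (a visually stable default for
cohorts of thousands; exposed as a parameter). Robustness iterations are
disabled: with a rare binary outcome the robust reweighting treats events
as outliers and flattens the curve.

Three recalibration routes address miscalibration driven by FIT
distribution differences between derivation and validation populations:

* `recalibrate_fit_scale()` — constant multiplication of FIT values; the
  factor can be estimated by matching the share of values ≥ 10 µg/g to a
  reference share. The achievable share is a step function with steps at
  the observed values, so the estimator scans them; it saturates at the
  share of nonzero values (scaling cannot make zeros positive).
* `recalibrate_fit_quantile()` — values map through the source empirical
  CDF (`rank/n`, mid-ranks for ties, so the zero-inflated mass maps to a
  single reference quantile) and then through the inverse reference CDF
  with linear interpolation. `reference_fit_synthetic_derivation()`
  supplies a *synthetic* reference reconstructed from published summary
  statistics of a derivation population (median 4, quartiles 4/8, 22.4%
  ≥ 10 µg/g, values floored at 4): the real distribution is not public, so
  this object demonstrates the mechanics rather than reproducing it.
* `logistic_recalibration()` — refit of the calibration line, returning a
  probability-mapping function; idempotent up to estimation noise, with a
  ridge-penalised fallback under separation.

`fit_spline_model()` provides the FIT-only comparator: a logistic model on
a natural cubic spline of `log(fit + 1)` with knots at the 5/35/65/95%
quantiles. On zero-inflated FIT data the lower knots coincide at zero and
are collapsed silently — fewer effective knots is the expected behaviour
there; only true degeneracy warns. In-sample, its calibration summary has
O/E = 1 exactly (a property of logistic maximum likelihood), which the
report tables use as a sanity row.

## Net benefit

`net_benefit()` implements `TP/n − FP/n · t/(1 − t)` and
`decision_curves()` evaluates named strategies plus treat-all/treat-none
on a default grid of 0.2%–5% risk in 0.1% steps — the band around the
cancer probabilities at which FIT-based referral operates. Recalibrated
model variants enter as additional strategies.

## Uncertainty

`bootstrap_ci()` resamples patients with replacement, recomputes the
metric per replicate — *including* matched-threshold re-selection, so
selection noise is part of the interval — and returns percentile bounds
taken as order statistics (`quantile type 1`; with `B = 1` both bounds are
the single replicate). Resampling is unstratified by default with a
`stratify` option for rare-event stability; replicates drawing a single
outcome class are redrawn up to ten times and then counted as failures,
with more than 5% failures an error. A `significant_reduction` flag
records whether the interval excludes zero; the sign convention (negative
= fewer referrals) is carried as metadata. `wilson_ci()` supplies Wilson
score intervals for monthly positivity proportions, with boundary cases
(`k = 0`, `k = n`) returned exactly.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes:

* **FIT values**: a point mass below the detection limit (reported 0,
  default probability 0.77) plus a lognormal tail censored at 400 µg/g.
  The default tail (`meanlog 2.43`, `sdlog 2.39`) was fixed analytically
  so that 12% of all values are ≥ 10 µg/g and 4.2% ≥ 100 µg/g, matching
  the zero-heavy marginal of a symptomatic primary-care population.
* **Predictors**: age truncated-normal (mean 62.7, SD 19.1, 18–103 y),
  41.4% male, lognormal platelets (median 267), normal MCV (91.5 ± 5.2 fL),
  drawn independently — their joint distribution with cancer arises only
  through the outcome model, a deliberate simplification flagged below.
* **Outcome**: Bernoulli draws from a fixed logistic surrogate on
  `log(fit+1)`, age, sex, PLT and MCV. The default coefficients were tuned
  once, by simulation against the default marginals, to give ~1.3% cancer
  prevalence and ~88% sensitivity of FIT ≥ 10 for cancer, with clinically
  signed effects (risk rises with FIT, age, male sex, platelets; falls
  with MCV). Because the outcome is drawn from a known model, scoring a
  cohort with its own generator must look calibrated — the
  parameter-recovery gate used in the tests.
* **Temporal drift** (`scenario_sixperiod()`): six calendar periods with
  positivity ramping 8.8% → 16.7% and prevalence 1.1–1.5%. Each period's
  joint (positivity, prevalence) target is met by solving the tail
  location (zero mass follows analytically from positivity, kept within
  0.50–0.97) against the expected outcome rate, computed by quadrature
  over a fixed profile sample — the outcome model itself never changes,
  implementing drift purely as case-mix. Where the prevalence target is
  outside the FIT mixture's reach (the final period pairs the highest
  positivity with the lowest prevalence), an age-location shift takes over
  as a secondary dial: a younger tested population, which is the
  phenomenon the drift describes.

What the generator does **not** emulate: correlations among predictors
(and thus realistic PLT/MCV–cancer joint structure beyond the model),
free-text symptoms, seasonality or within-period volume ramps (FIT dates
are uniform within months), repeat testing, device biochemistry beyond a
binary flag, and cancers diagnosed outside the follow-up window. Passing
tests on this cohort therefore demonstrate correctness of the *metrics and
machinery* under a known truth, not transportability claims about any real
population.

## Data preparation rules

Reported FIT values are censored (`< 1.3 → 0`, `> 400 → 400`, idempotent);
a separate floor at 4 µg/g exists for feeding externally derived equations
and is never used for positivity classification. Blood results are taken
from a closed `[−365, +14]`-day window around the FIT, excluding
measurements after the cancer date, keeping the record closest to the FIT
— an equidistant pre/post pair resolves to the earlier record, since
pre-test bloods cannot be influenced by post-test workup. The outcome is
cancer within a configurable follow-up window (180 days default, 365 for
sensitivity analysis); a cancer dated before the FIT is never outcome 0
but a prior-cancer exclusion. Exclusions apply in a fixed order (non-GP
request, under-18, insufficient follow-up — including cancer patients,
whose retention would bias prevalence — prior cancer, missing bloods) so
the tally is reproducible flow-diagram accounting. Calendar dates are
whole days; period boundaries are month-based, with uncovered months
labelled `unassigned` (kept in whole-cohort analyses, dropped from period
analyses).

## Problem sizes and numerical tolerances in the test-suite

The packaged tests run the generator at up to 50,000 patients for
parameter-recovery gates (O/E and slope within [0.9, 1.1]), use 200 outer
replicates with 200 bootstrap resamples for the coverage check of a
zero-true-value reduction (accepting 90–99% coverage), and verify the
matched-threshold selector against exhaustive enumeration on 1000 random
instances of up to 20 patients. Monte-Carlo reference values (e.g. the
null distribution of average precision) are estimated by replication
rather than asymptotic formulas, since the zero-inflated, rare-event
setting makes normal approximations unreliable at these sizes. These sizes
were chosen as the smallest that make the stochastic gates stable under
their stated tolerances.

## Known limitations

* The surrogate model is a stand-in with invented (though
  clinically-signed) coefficients; absolute referral-reduction numbers on
  synthetic cohorts are not estimates for any real population.
* The quantile-recalibration reference is reconstructed from published
  quartiles and positivity only.
* Matched thresholds are order statistics; their period-to-period
  transfer is noisy at realistic cancer counts (~100 per period), and the
  prospective analysis should always be read together with its bootstrap
  intervals.
* Percentile bootstrap only; no BCa or analytic intervals.
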