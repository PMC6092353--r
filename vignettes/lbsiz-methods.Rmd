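---
title: "Methods: allometric body-shape z-scores and cardiovascular risk"
author: "lbsiz package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allometric body-shape z-scores and cardiovascular risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbsiz)
```

## The index

Body mass index (weight/height², kg/m²) and waist circumference (WC) are the
workhorse obesity measures in epidemiology, but both conflate abdominal fat
with overall body size. A Body Shape Index (ABSI) addresses this by scaling
WC allometrically for weight and height; the standard definition is
WC / (BMI^(2/3) · height^(1/2)) = WC · height^(5/6) / weight^(2/3). ABSI's
scaling exponents, however, differ across populations, and its raw values are
awkwardly scaled for regression work.

This package builds the log-transformed, z-scored version of the index for a
reference population. Writing the allometric model as a log–log regression,

    ln(WC) = c + a·ln(weight) + b·ln(height) + ε,

the **LBSI** of a participant is the residual

    LBSI = ln(WC) − c − a·ln(weight) − b·ln(height),

with WC and height in metres and weight in kilograms, natural logarithms
throughout. The **LBSIZ** is its z-score against reference constants:

    LBSIZ = (LBSI − mean_ref) / sd_ref.

The packaged Korean reference set (`reference_constants("korean_kns_2018")`)
is c = −2.69, a = 0.73, b = −1.06, mean_ref = −0.02, sd_ref = 0.06. With
these constants a typical participant (WC 82.5 cm, 63 kg, 1.60 m) has
LBSI = −0.0287, consistent with the reference mean:

```{r}
compute_lbsi(anthropometry(0.825, 63.0, 1.60))
```

Because the constants are printed to two/three figures, they are used
exactly as published; `fit_allometric_exponents()` re-estimates them on any
cohort (ordinary least squares on the log scale), and
`estimate_standardization()` re-derives the z-score constants (sample SD,
n − 1 denominator), but neither is ever substituted silently for the
published set.

**Unit convention.** The literature leaves the units of the LBSI formula
implicit. Only metres/kilograms with natural logs reproduces the published
reference mean of −0.02 at typical cohort anthropometry, so that is the
package convention; `load_cohort()` accepts centimetre inputs and converts.

**ABSI sign caveat.** Some sources print ABSI as
WC/(weight^(2/3) · height^(5/6)), with height's exponent in the denominator —
the opposite sign from the standard definition. `compute_absi()` defaults to
the standard (`"krakauer"`) convention and emits a warning when the
`"as_printed"` variant is requested, so no analysis silently mixes the two.
LBSI is unaffected: its exponents are explicit parameters.

Since LBSIZ is a strictly increasing affine function of LBSI, every rank
statistic (Spearman correlation, AUC) is identical for LBSI, LBSIZ, and ABSI
computed with the same exponents; the test suite asserts this to machine
precision.

## The comparator risk score

The Framingham general-CVD score is used as the discrimination benchmark.
The package ships the continuous (Cox-model) D'Agostino 2008 general
cardiovascular formulation — sex-specific coefficients on log-age, log-total
cholesterol, log-HDL, log-SBP (treated/untreated), current smoking and
diabetes, with 10-year risk 1 − S0^exp(lp − mean_lp). This formulation was
chosen over the older hard-CHD score because the composite endpoint analysed
here (MI, CHD, heart failure, cerebrovascular and peripheral arterial
disease) corresponds to general CVD. The version is a parameter
(`frs_coefficients()`), alternative tables load from a CSV of the same
layout, and the version id is carried in the object. No recalibration to
non-US incidence is attempted. Diabetes is scored from the flag alone, so
records without glucose measurements remain scorable.

## Survival analysis

- **Follow-up construction** (`follow_up_years()`): years =
  days/365.25 from baseline to the earlier of the event date and the
  administrative end of follow-up (default 2012-12-31); events after the end
  date are censored.
- **Kaplan–Meier and log-rank** (`kaplan_meier()`, `logrank_test()`): the
  product-limit estimate with Greenwood-based log-scale 95% intervals, via
  the survival package. Default dichotomizations for curve displays are
  BMI ≥ 25 kg/m² (the Asian-Pacific obesity cutoff), WC ≥ 90/85 cm
  (men/women) and LBSIZ ≥ 0; all three are configurable because published
  analyses rarely state their exact cutoffs.
- **Cox models** (`fit_cox()`): partial-likelihood maximization by
  Newton–Raphson with the Efron tie correction by default (Breslow
  available); Efron and Breslow coincide exactly on untied data, which the
  suite checks. The design matrix is rank-checked up front so collinear
  covariates raise an error rather than NA coefficients. Confidence
  intervals are Wald on the log-HR scale throughout.
- **Deciles** (`decile_groups()`): rank-based assignment
  d = ⌈10·rank/n⌉ with minimum ranks for ties, so tied values at a boundary
  fall in the lower decile and sizes differ by at most one without ties.
  Decile 1 is the reference (HR ≡ 1, no interval) in
  `decile_hazard_ratios()`.
- **Restricted cubic splines** (`rcs_basis()`, `spline_hazard_curve()`):
  Harrell's truncated-power basis, normalized by (t_k − t_1)², linear beyond
  the boundary knots; 4 knots by default at the 5th/35th/65th/95th
  percentiles (Harrell's standard placement — analyses that state only
  "4 knots" are conventionally read this way). The hazard-ratio curve is
  anchored at HR = 1 at the exposure median (configurable), with delta-method
  intervals on the basis contrast, and the joint Wald test of the nonlinear
  terms is reported as the test of departure from log-linearity.

## Discrimination

The ROC outcome is the binary 10-year event indicator, ignoring censoring
time: follow-up here is administratively closed at a fixed horizon with
essentially complete ascertainment, which is the one situation where the
fixed-window binary reading of an ROC is defensible. This caveat matters for
cohorts with substantial early dropout, where a time-dependent AUC would be
needed (out of scope).

`auc_mann_whitney()` computes the midrank Mann–Whitney AUC; `roc_curve()`
additionally returns the empirical curve (the trapezoidal area equals the
midrank AUC identically, asserted to 1e−12) and DeLong's
structural-component variance. `delong_compare()` performs the paired
correlated-AUC test, retaining per-subject placement values; the degenerate
case of identically-ranking scores returns z = 0, p = 1. Paired p-values are
two-sided normal with no multiplicity correction. The implementation is
cross-checked in the suite against an independent one (pROC) and against a
delete-one jackknife oracle on small samples.

The "integrated" score (`integrated_auc()`) combines the Framingham linear
predictor with one obesity parameter by maximum-likelihood logistic
regression on the same data, takes the fitted linear predictor as the
combined score, and compares it to the base score with the paired DeLong
test. Two caveats are deliberate and documented rather than hidden: the
combination is fitted in-sample (so the combined AUC cannot be worse
in-sample), and DeLong on nested fitted scores is known to be
anti-conservative near the null. The package treats this as a descriptive
improvement measure, matching common practice.

## The synthetic cohort

KOGES-style cohort data are not publicly downloadable, so the package
includes a generator (`generate_cohort()`) that emulates the structure the
analysis assumes, making every stage testable end to end. Defaults were
fixed once from the published marginals of a middle-aged Korean cohort
(c. 2001) and are not tuning knobs:

| Component | Default | Source of the value |
|---|---|---|
| n, sex | 8485, 48% male | published sex counts |
| Age | 52.1 ± 8.8 y, truncated 40–69 | published |
| Height/weight | men 166.4 cm / 66.6 kg, women 153.0 / 57.5; log-SDs 0.035 / 0.135, log-correlation 0.45 | realistic Korean anthropometry; reproduces BMI 24.5 ± 3 and WC 82.5 ± 8.7 |
| Waist | allometric relation + residual N(−0.02, 0.06²) | the LBSI reference constants; the −0.02 offset reflects that the scoring coefficients come from an external reference population |
| SBP 121 ± 18, TC 190.4 ± 35.4, HDL 44.7 ± 10, TG 160.8 ± 104.8 (log-normal, truncated < 400), glucose 86.8 ± 20.5, HbA1c 5.8 ± 0.9 | published means/SDs | |
| Smoking 58/16/26%, diabetes 12%, hypertension 32%, dyslipidaemia 48% | published prevalences | |
| Outcome | exponential baseline, rate calibrated to a 7% 10-year event fraction; log-hazard 0.3·LBSIZ + 0.1·z_BMI² ; censoring at 10 y | event fraction published; the linear-in-LBSIZ / J-shaped-in-BMI hazard is the phenomenon under study, with 0.1 giving HR ≈ 1.9 at |z_BMI| = 2.5, the magnitude seen in published dose–response curves |

Event times use inverse-transform sampling from S(t)^exp(η); Weibull shapes
other than 1 are available. The baseline rate is calibrated against the
realized linear predictors by root-finding, so the marginal event fraction
matches the target in expectation whatever the betas. LDL is always derived
through the Friedewald equation (a validated invariant), and medication
flags are nested within their parent conditions. One root seed is split into
three stage seeds drawn up front (anthropometry → covariates → outcomes), so
extending the covariate model cannot perturb anthropometry draws.

**What the generator does not emulate**: the joint dependence of risk
factors on age, sex and adiposity (marginals only, beyond the allometric
relation); the five CVD sub-diagnoses; loss to follow-up and competing
mortality; sex-specific smoking prevalence. Consequently, passing tests
demonstrate that the statistical machinery recovers known structure from
data of this shape — not that real-cohort effect sizes are reproduced. In
particular the synthetic Framingham score discriminates only weakly, since
its inputs carry no simulated effect on the hazard beyond their correlation
with the obesity measures.

## Numerical choices

- Quantile type 7 (R default) for knot placement; decile assignment is
  rank-based, independent of quantile interpolation.
- t-tests in `baseline_table()` are classical equal-variance by default
  (`var_equal = FALSE` for Welch); chi-square without continuity correction
  (`yates = TRUE` available for 2×2).
- Friedewald LDL is withheld (NA, with a warning) at TG ≥ 400 mg/dL.
- Cox convergence follows coxph's Newton iterations; `fit_cox()` records
  iteration count, convergence flag and the final partial log-likelihood.
- Degenerate inputs fail loudly: one-class ROC labels, constant decile
  exposures, zero-variance standardization, collinear designs and empty
  cohorts are all errors, not NaNs.

## Validation problem sizes

The test suite validates each stage at the scale where its statistical
guarantee is sharp while staying lightweight: exact oracles on toys
(6-subject Cox brute force, hand-worked log-rank and ROC tables), n = 5000
against the exponential closed form, 200-replicate coverage and
coefficient-recovery studies (n = 2000 and 8000), a 2000-replicate DeLong
type-I study at n = 500, and 20–60 replicates of the full n = 8485 cohort
for the dose–response shape checks (interior J-shape minimum for BMI,
preserved linearity for LBSIZ, AUC ordering). The allometric
coefficient-recovery study spans the full adult anthropometric range rather
than the narrower cohort spread: the model's intercept is evaluated at the
log-space origin, and a narrow design does not identify it to the ±0.02
precision the check asserts.

## Limitations

The package quantifies abdominal adiposity via a single residual index; it
does not model fat distribution directly (no CT/DXA), does not provide
time-dependent discrimination measures or competing-risks models, and makes
no attempt to recalibrate the Framingham score. Synthetic results
characterise the methods, not any real population.
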