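# lbsiz

Cardiovascular epidemiology toolkit around the **z-score of the
log-transformed A Body Shape Index (LBSIZ)** — an abdominal-obesity measure
that scales waist circumference allometrically for weight and height, then
standardizes the log residual against a reference population.

BMI (weight/height², kg/m²) and waist circumference (WC) both conflate
abdominal fat with overall body size, and both show J-shaped ("obesity
paradox") associations with cardiovascular events. LBSIZ is built to be
nearly independent of BMI while tracking central adiposity. Given the
log–log allometric model ln(WC) = c + a·ln(weight) + b·ln(height) + ε, the
index is

```
LBSI  = ln(WC) − c − a·ln(weight) − b·ln(height)      (WC, height in m; weight in kg)
LBSIZ = (LBSI − mean_ref) / sd_ref
```

with the packaged Korean reference set c = −2.69, a = 0.73, b = −1.06,
mean_ref = −0.02, sd_ref = 0.06.

The package is for biostatisticians and cardiovascular epidemiologists who
want to score cohorts with LBSIZ and run the full comparative risk analysis
it belongs in:

- index construction and in-sample re-estimation of allometric exponents
  and standardization constants (`compute_lbsi`, `fit_allometric_exponents`,
  `estimate_standardization`), plus BMI, ABSI and Friedewald LDL;
- Framingham general-CVD risk as the discrimination comparator
  (`frs_risk10`, D'Agostino 2008 continuous formulation, packaged
  coefficients);
- ROC/AUC with DeLong correlated-AUC comparison and Framingham-plus-index
  "integrated AUC" (`roc_curve`, `delong_compare`, `integrated_auc`);
- Kaplan–Meier/log-rank, Cox proportional hazards, decile hazard ratios and
  4-knot restricted-cubic-spline dose–response curves (`kaplan_meier`,
  `fit_cox`, `decile_hazard_ratios`, `spline_hazard_curve`);
- a calibrated synthetic-cohort generator (`generate_cohort`) emulating a
  middle-aged Korean cohort (WC 82.5 ± 8.7 cm, BMI ≈ 24.5, ~7% 10-year
  event rate, proportional hazards linear in LBSIZ and J-shaped in BMI),
  so the entire pipeline is reproducible without access data;
- an end-to-end pipeline (`run_full_analysis`) and a thin CLI
  (`inst/cli/lbsiz-pipeline.R`: `simulate`/`score`/`analyze`/`report`).

## Worked example

Score one participant (WC 82.5 cm, 63 kg, 1.60 m) and run the full analysis
on a default synthetic cohort:

```r
library(lbsiz)

lbsi <- compute_lbsi(anthropometry(0.825, 63.0, 1.60))
lbsi                      # -0.0286564
standardize_lbsi(lbsi)    # -0.1442733

report <- run_full_analysis(cohort_config(n = 8485, seed = 1))
report
#> Cohort analysis report
#>   n = 8485 participants, 624 events (7.4%)
#>   AUC: bmi 0.507, wc_cm 0.555, lbsiz 0.595, frs_lp 0.519
#>   DeLong: lbsiz_vs_bmi p=3.4e-07, lbsiz_vs_wc_cm p=0.00144
report$spline_tests
#>   measure statistic df  p_nonlinear
#> 1     bmi 20.972841  2 2.791294e-05
#> 2   wc_cm  4.540308  2 1.032963e-01
#> 3   lbsiz  1.993049  2 3.691602e-01
```

Reading the output: the participant's LBSI (−0.0287) sits near the
reference mean, so their z-score is mildly negative. In the synthetic
cohort — whose hazard is linear in LBSIZ and quadratic in standardized
BMI by construction — LBSIZ discriminates events best (AUC 0.595), WC is
intermediate and BMI near chance, the paired DeLong tests confirm the AUC
gaps, and the spline nonlinearity tests recover the built-in shape: strong
departure from log-linearity for BMI (the J-shape), none for LBSIZ.
`report` also carries the baseline characteristics table, Kaplan–Meier
curves with log-rank tests, and adjusted decile hazard ratios;
`write_report(report, dir)` serializes everything as CSV + JSON.

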