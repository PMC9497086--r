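# iscore

Consensus Immunoscore scoring and survival analysis for colon cancer
cohorts.

## The problem

The density of tumor-infiltrating CD3+ and cytotoxic CD8+ T cells carries
prognostic information in stage I–III colon cancer beyond the AJCC/UICC-TNM
staging system. The consensus Immunoscore summarizes that immune contexture
in a single standardized assay: CD3 and CD8 cell densities (cells/mm²) are
measured by digital pathology in two regions — the tumor core (CT) and the
invasive margin (IM) — and each of the four densities is converted into a
percentile of a reference distribution. The patient's score is

&nbsp;&nbsp;&nbsp;&nbsp;*S* = mean of the four percentiles ∈ \[0, 100\],

binned into the pre-defined consensus categories:

| scheme | bins |
|---|---|
| two   | Lo \[0, 25\], Int+Hi (25, 100\] |
| three | Lo \[0, 25\], Int (25, 70\], Hi (70, 100\] |
| five  | I0 \[0, 10\], I1 (10, 25\], I2 (25, 70\], I3 (70, 95\], I4 (95, 100\] |

`iscore` implements this scoring procedure (mid-rank percentiles, slide
quality control with the ≤152 AU staining-intensity rule, all three
category schemes) together with the survival-analysis toolkit used to
evaluate it in multicenter cohorts: the time-to-recurrence (TTR), overall
survival (OS) and disease-free survival (DFS) endpoints; Kaplan–Meier
landmark rates with log(−log) confidence intervals; log-rank and ordered
trend tests; center-stratified Cox proportional-hazards models with
Efron/Breslow ties and monotone-likelihood (Inf/NA) reporting; Harrell's
concordance with a seeded bootstrap interval; restricted mean survival
time (RMST) comparisons; likelihood-ratio tests of added prognostic value;
and chi-squared relative-importance proportions.

Because patient-level data of published Immunoscore cohorts are not
public, the package ships a first-class synthetic-cohort generator whose
recurrence hazard follows a known proportional-hazards model on the true
Immunoscore category and clinical covariates, so every stage of the
pipeline is testable against generating truth. Functions are data-frame
first and return tibbles, so the whole analysis chains with the pipe.

## Worked example

```r
library(iscore)

cfg      <- sim_config(n_patients = 423, seed = 42)   # study-scale defaults
cohort   <- generate_cohort(cfg)
scored   <- score_cohort(cohort$markers, cohort$reference)
endpoints <- derive_endpoints(cohort$patients)

cohort
#> <synthetic_cohort> 423 patients, 68 recurrences, 59 deaths; Lo/Int+Hi = 147/276

scored$scores[1:3, c("patient_id", "mean_percentile", "is2", "is3", "is5")]
#>   patient_id mean_percentile is2    is3   is5
#> 1 P0001                 32.9 Int+Hi Int   I2
#> 2 P0002                 81.2 Int+Hi Hi    I3
#> 3 P0003                 55.8 Int+Hi Int   I2

bivariable_table(cohort$patients, scored$scores, endpoints,
                 variables = "is2")[, c("level", "n", "pct", "rate_60",
                                        "hr", "hr_low", "hr_high", "hr_p")]
#>    level   n  pct rate_60   hr hr_low hr_high   hr_p
#> 1     Lo 147 34.8    80.7 1.62   1.01    2.61 0.0474
#> 2 Int+Hi 276 65.2    88.5 1.00     NA      NA     NA
```

Reading the table: 147/423 patients (34.8%) are Immunoscore Lo; their
5-year recurrence-free rate is 80.7% against 88.5% for Int+Hi, and the
unadjusted center-stratified hazard ratio of recurrence for Lo vs Int+Hi
is 1.62 (95% CI 1.01–2.61, Wald p = 0.047) — this cohort was generated
with a true HR of 1.9. The multivariable model adjusts for the clinical
covariates and reports the likelihood-ratio test for the added value of
the score:

```r
multivariable_model(cohort$patients, scored$scores, endpoints)
#> <is_multivariable> n = 275, events = 43
#>   term          ...    hr conf_low conf_high  p_value
#> 1 immunoscoreLo ...  1.83    0.983      3.41  0.0566
#> ...
#> LRT for adding Immunoscore: chi2 = 3.525 (df 1), p = 0.0605
```

(The multivariable fit runs on the 275 complete cases; MSI status is
undetermined for about a third of patients, as in the cohorts this
emulates.) `subgroup_analysis()` reruns the machinery on MSS patients,
stage II patients, or the T4/VELIPI histopathology risk groups;
`age_association()` tests densities and score against age bins;
`compare_cohorts()` contrasts two cohorts' covariates; `autoplot()` and
`plot_km_groups()` draw the fitted curves.

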