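---
title: "Methods: consensus Immunoscore scoring and cohort survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus Immunoscore scoring and cohort survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscore)
```

## The scoring model

The consensus Immunoscore condenses four density measurements — CD3+ and
CD8+ T cells (cells/mm²) in the tumor core (CT) and the invasive margin
(IM) — into a single prognostic score. Each density is converted into a
percentile of a reference distribution for its (marker, region) pair, and
the patient's score is the arithmetic mean of the four percentiles,
binned into the pre-defined two-, three- and five-category schemes.

Two numerical conventions deserve spelling out, because the consensus
description fixes the cut-points but not the arithmetic around them:

* **Mid-rank percentiles.** `density_percentile()` scores a density $d$
  against a reference vector $r$ of length $n$ as
  $100\,(\#\{r_i < d\} + \tfrac12 \#\{r_i = d\})/n$. Ties count half.
  This choice is symmetric (a reference scored against itself averages to
  exactly 50), deterministic, bounded in $[0, 100]$ and monotone in $d$;
  alternatives such as `ecdf`-style right-continuous ranks are none of
  the first two.
* **Boundary values belong to the lower bin.** The published interval
  notation (0–25, >25–70, >70–100; I3 >70–95, I4 >95–100) puts the
  boundary in the lower category, so a mean percentile of exactly 25 is
  Lo/I1, 70 is Int/I2, and 95 is I3. The two-category split uses the same
  boundary: Lo = [0, 25], Int+Hi = (25, 100]. With these conventions the
  three schemes nest exactly ({I0, I1} = Lo, I2 = Int, {I3, I4} = Hi),
  which the test suite verifies on a percentile grid of step 0.01.

The reference distribution is an explicit input rather than a baked-in
table: the consortium's training reference is unpublished, so the package
accepts any reference file (or the cohort's own densities) and records
which one was used. `generate_reference()` provides a synthetic stand-in
drawn from the generator's density model.

**Quality control.** `apply_qc()` excludes a slide when either region is
unavailable, staining intensity is ≤ 152 AU (the threshold is a
configurable opaque number in instrument-specific units), the slide is
flagged damaged, or antigen retrieval failed more than 3 times. When
several rules match, the recorded reason follows the fixed priority
missing region → low intensity → damaged slide → retrieval failures, so
QC reports are deterministic. The damaged-slide flag is an input; it is
never inferred.

## Endpoints

All times are months from surgery. OS is time to death from any cause;
TTR is time to disease recurrence, with death without recurrence treated
as censoring at the death time (the standard TTR convention; the source
definitions are silent on censoring); DFS is time to the first of
recurrence or death. The DFS event indicator is therefore the logical OR
of the TTR and OS indicators — a conservation property the tests assert
patient by patient. Median follow-up uses the reverse Kaplan–Meier
estimator (event flags swapped) with a log(−log) interval.

**Risk groups.** Stage II analyses use the histopathology partition built
from T4 extent and VELIPI (vascular emboli, lymphatic or perineural
invasion). The published text and figure caption swap the and/or in the
definitions of "high" and "very high" risk, and the printed group sizes
overlap; the package imposes the only self-consistent disjoint reading —
very high = T4 and VELIPI+, high = exactly one of the two, low = neither —
and `assign_risk_group()` documents it. The combined
Immunoscore-by-risk table row uses T4 & VELIPI+ against all others, as in
the published table layout.

## Survival engine

The standard estimators are delegated to the `survival` package and
exposed behind a stable surface; choices that the surface fixes:

* **Ties.** Efron's approximation by default (monthly follow-up produces
  ties), Breslow selectable. Both agree exactly on tie-free data (tested).
* **Convergence and monotone likelihood.** Cox fits run Newton iterations
  with step-halving (tolerance 1e-9, ≤ 50 iterations). A coefficient
  diverging beyond |β| > 15 is treated as monotone likelihood — e.g. a
  level with zero events — and reported as HR = Inf with CI (0, Inf) and
  p = NA, mirroring how such rows appear in published tables, rather than
  raising an error.
* **Confidence intervals.** Kaplan–Meier intervals are computed on the
  log(−log S) scale, which keeps landmark-rate intervals inside
  [0, 100] even near S = 1.
* **RMST.** Restricted mean survival time is the area under the KM curve
  up to τ, with the standard large-sample variance accumulated over KM
  increments. τ defaults to the smaller of the two groups' largest
  observed times, since no truncation time is published; it is a visible
  argument.
* **Trend test.** The "trend p" across ordered categories is a score
  test with equally spaced integer scores: with the log-rank
  observed-minus-expected vector $O - E$ and covariance $V$ from the
  k-group test, the statistic is $(c'(O-E))^2 / (c'Vc)$ on 1 df. The
  variant behind published trend p-values is unstated; this choice is
  documented, not inferred from results, and is invariant to reversing
  the score direction.
* **Concordance.** Harrell's C counts score ties as one half over the
  pairs comparable under right censoring. The interval is a seeded
  percentile bootstrap (200 resamples by default) over patients, since
  the original interval method is unstated.
* All p-values are two-sided; no multiplicity correction is applied
  (none is described for the analyses this mirrors).

Bivariable tables apply the complete-case rule per variable (published
denominators vary by row, e.g. MSI determined in a subset only), never
global listwise deletion, and the unadjusted hazard ratios are
center-stratified by default — consistent with a center-stratified
bivariable description — with `stratify_center = FALSE` available since
the published table's "unadjusted" label leaves it ambiguous. In the
five-category scheme the HR reference is I3 and the RMST reference is I4,
matching the published layout where I4 has zero events and is therefore
reported Inf/NA in the HR column.

## The synthetic-cohort generator

`sim_config()` defaults encode the cohort the analyses emulate: 423
patients from four Asian centers (AHM, SAP, TOK, XIA), stage I/II/III mix
15.8/59.4/24.8%, 54.6% male, age 64.7 ± 12.1 years, VELIPI+ 71.2%, MSI-H
9.6% among the ~64% of patients with determined status, chemotherapy in
62.7% (restricted to stage II–III), and ~15% recurrence with ~74 months
median follow-up.

The generating outcome model is an exponential proportional-hazards law:
the recurrence hazard is `baseline_hazard_rate` × exp(β·Lo + clinical
terms), where Lo is the patient's *true* two-category Immunoscore —
computed by the same scoring path against the generated reference — and
the default β is log(1.9), the headline bivariable effect size. Death
combines an exponential post-recurrence process and small background
mortality, so TTR, OS and DFS genuinely differ; censoring is
administrative at 84 months minus a uniform 0–20 month entry stagger,
giving a reverse-KM median follow-up near 74 months. The exponential
baseline is deliberately the simplest law under which the Cox estimator
is unbiased, which is what the parameter-recovery tests rely on.

Densities are correlated log-normals via a Gaussian copula with a single
exchangeable correlation (0.72), the one-parameter family that reproduces
the right skew of density data. The published work reports no density
distribution parameters, so the log-means/SDs are plausibility choices
(medians of roughly 180–650 cells/mm² across the four marker–region
pairs). The reference distribution is drawn from the same family shifted
upward by 0.42 on the log scale, emulating a training reference from a
more highly infiltrated population; with the default correlation this
yields roughly the published category mix (≈37% Lo, Hi in the low
teens against the published 16%). These
values were fixed once against the published marginal percentages and are
not tuned per analysis.

What the generator does *not* emulate: slide images or spatial cell
coordinates (densities are drawn directly), center effects on densities
or outcomes beyond the stratification labels, non-proportional hazards,
informative censoring, and correlation between Immunoscore and clinical
covariates (MSI-H tumors, for instance, are not given higher densities).
Passing recovery and calibration tests therefore demonstrates the
correctness of the estimators under the stated model, not the clinical
performance of the score on real data.

`inject_qc_failures()` degrades a Bernoulli subset of measurements
(default 5%) so that QC has something to find: half get staining
intensity ≤ 152 AU, half lose the invasive margin. Flagged ids are
recorded in the cohort's truth record, which is always serialized next to
the data (`truth.json`) so recovery tests are self-describing.

Determinism: the whole cohort is a pure function of the configuration.
The reference uses the seed itself, patient-level draws use seed + 1, and
QC injection seed + 2, so regenerating any component in isolation
reproduces it bit for bit.

## Problem sizes used by the test suite

Oracle-equivalence tests run at deliberately tiny sizes where brute force
is exact: exhaustive label permutation at n = 8, grid search of the
partial likelihood at step 1e-4, O(n²) pair enumeration at n = 30.
Parameter recovery uses one cohort of n = 2000 at HR 1.9 plus 200
replicates of n = 2000 under the null for CI coverage; calibration uses
500 replicates of n = 240 for the Kolmogorov–Smirnov uniformity checks of
log-rank, trend and LRT p-values. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances (3 binomial SEs for coverage,
KS at α = 0.01) while keeping the suite around a minute.

## Known limitations

* The package scores against whatever reference it is given; with the
  cohort-as-its-own-reference option, percentiles are in-sample and the
  category mix is constrained by construction.
* The Cox machinery has no time-varying covariates, competing-risks
  estimators or frailty terms; stage II chemotherapy-benefit analyses are
  out of scope by design.
* Monotone-likelihood reporting (Inf/NA) is triggered by a coefficient
  threshold (|β| > 15); pathological near-separation below the threshold
  is reported as a finite, very wide interval.
* The C-index bootstrap resamples patients, not centers; with very few
  centers and strong center effects a clustered bootstrap would be more
  appropriate.
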