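---
title: "Dried-blood-spot TDM of lamotrigine: models, validation statistics and outlier screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dried-blood-spot TDM of lamotrigine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbstdm)
```

## The problem

Therapeutic reference ranges for antiepileptic drugs are defined on plasma,
but dried blood spots (DBS) measure whole blood. The two differ because a
drug partitions between plasma and blood cells, and the measured DBS
concentration depends on the patient's haematocrit (Hct, the cell volume
fraction of blood). `dbstdm` implements the quantitative half of a DBS
monitoring workflow for lamotrigine (LTG) and its main metabolite,
lamotrigine-N2-glucuronide (LTG-N2-GLU): converting DBS concentrations to
plasma equivalents, cross-validating DBS against plasma, computing the
standard bioanalytical validation statistics, and screening
metabolite-to-parent ratios (MPR) for patients with altered metabolic
clearance.

## The partition model

Whole blood at haematocrit $h$ is a volume-weighted mixture of plasma and
blood cells. With $K = c_{BC} / c_{PL}$ the blood-cell-to-plasma partition
coefficient, mass balance gives

$$c_B = c_{PL}\,\big[(1 - h) + K h\big],$$

so a plasma-equivalent concentration is recovered from a DBS measurement as
$c_{PL} = c_B / ((1-h) + Kh)$ (`plasma_from_blood()`). Two limits matter
here: $K = 0$ describes an analyte excluded from cells — glucuronide
metabolites have very limited membrane permeability, so the metabolite uses
the plain haematocrit correction $c_{PL} = c_B/(1-h)$ — and $K = 1$ makes
blood and plasma concentrations equal at every haematocrit. Lamotrigine
itself is lipophilic and accumulates in cells ($K \approx 1.57$), so
correcting for haematocrit alone is not sufficient.

`estimate_k()` fits $K$ by least squares on the plasma scale,
$\min_K \sum_i \big(c_{PL,i} - c_{B,i} / ((1-h_i) + K h_i)\big)^2$. The
problem is one-dimensional, so a bracketed scalar minimizer on $[0, 50]$
(tolerance $10^{-9}$) is used instead of a generic multivariate optimizer:
it is deterministic, derivative-free and cannot diverge. Identifiability
requires haematocrit variation across records; with all $h_i$ identical
the fit still runs but attaches a warning, because a single mixing ratio
cannot be separated from an assay scale factor. Confidence intervals are
leave-one-out jackknife (t quantile, $n-1$ df); a percentile bootstrap is
available behind an explicit seed. Records from both sampling timepoints
(trough and peak) are pooled by default and a `timepoint` filter is
exposed, since partitioning is assumed concentration-independent over the
0.1–20 µg/mL analytical range — saturable partitioning is out of scope.

## Method comparison

`compare_dbs_plasma()` reproduces the standard four-panel cross-validation:

1. Deming regression of the DBS concentration (response) on measured
   plasma (comparator). With errors in both assays, ordinary least squares
   would attenuate the slope; Deming regression models both. The slope of
   this panel is the blood-to-plasma concentration ratio — about
   $\overline{1-h}$ (≈ 0.5–0.6) for the cell-excluded metabolite and
   $\overline{(1-h) + Kh}$ (> 1) for the parent.
2. Plasma concentrations calculated from DBS via the partition model.
3. Deming regression of calculated on measured plasma; a slope interval
   covering 1 indicates a successful conversion.
4. Bland–Altman agreement for both the raw and the converted comparison:
   mean difference, SD ($n-1$), limits of agreement mean ± 1.96 SD, and a
   t-based CI of the mean difference (the convention when the CI method is
   otherwise unspecified).

Regression orientation deserves a note: the slopes reported for this kind
of study are blood-to-plasma ratios, so the package regresses blood
(response) on plasma (comparator), even though comparison plots are often
drawn with plasma on the vertical axis. `lambda`, the ratio of y-error to
x-error variance, defaults to 1 (both assays treated as equally
imprecise); as `lambda` grows the fit approaches OLS of y on x. The
weighted mode uses weights $1/\bar m_i^2$ with $\bar m_i = (x_i+y_i)/2$,
the standard weighted-Deming convention when the error is proportional to
concentration (constant CV), which is what the QC data show; the
closed-form solution with weighted moments is iterated until the slope is
stable to $10^{-10}$. Both timepoints of a subject enter as independent
pairs — a repeated-measures adjustment is a known limitation, and subject
ids are retained for future clustering.

## Validation statistics

The `assay_validation` functions implement the usual bioanalytical
acceptance criteria: non-weighted linear calibration over 11 levels
(0.1–20 µg/mL) with per-level back-calculated bias (a 1/x² weighted
option exists, default off, matching the validated design); LLOQ passing
when CV and |bias| ≤ 20% and the signal is ≥ 5-fold the blank; QC
accuracy/precision with bias% = 100(mean − nominal)/nominal and CV% using
the sample SD (the $n-1$ convention, since the guideline leaves it
unstated); inter-day statistics pooling all replicates across days rather
than averaging daily means; relative matrix effect as the RSD of
calibration slopes across ≥ 3 blood lots (pass below 4%); recovery as
100·A/B; haematocrit (25–55%) and spot-volume effects against ±15%; and
storage stability as percent of freshly spiked samples within 100 ± 15%.
Back-calculated values below the LLOQ are flagged (`flag_blq()`), retained
in validation computations, and meant to be excluded from patient reports.

Haematocrit units are a perennial source of confusion: tables print
"Hct %" while the partition algebra needs a fraction. The package stores
fractions and coerces inputs in [15, 100] by dividing by 100 — no human
haematocrit is below ~15%, so the mapping is unambiguous; values between 1
and 15 are rejected as malformed rather than silently rescaled.

## MPR screening

The trough metabolite-to-parent ratio is a proxy for glucuronidation
clearance: enzyme induction (e.g. co-medication with phenytoin) raises it,
inhibition or reduced-activity UGT variants lower it — and unlike the
parent concentration alone, it separates altered clearance from poor
compliance. `summarize_cohort()` computes per-subject MPRs, cohort
statistics, Tukey's fences at quartiles ± 1.5·IQR, and a Grubbs test.

Quartiles are Tukey hinges (medians of the median-inclusive halves, as in
`fivenum()`); on the worked nine-patient example hinge and
linear-interpolation quartiles give the same fences, so the convention is
documented but not result-changing there. The Grubbs statistic is
$G = \max_i |x_i - \bar x| / s$ with the two-sided p-value
$p = \min(1,\, 2n\,P(T_{n-2} \ge t))$,
$t = \sqrt{n(n-2)G^2 / ((n-1)^2 - nG^2)}$; $G^2 \ge (n-1)^2/n$ (the
attainable maximum) yields $p = 0$ exactly. Because ratio data are
right-skewed, the test defaults to the log scale (`scale = "raw"`
available): on the worked example only the log scale reproduces the
reported borderline p-value (≈ 0.087 from the printed three-decimal
ratios, against ≈ 0.089 reported), while the raw scale gives ≈ 0.29. The
scale is surfaced as an option rather than asserted as the original
authors' computation.

```{r mpr}
summarize_cohort(ltg_trough_cohort())
```

## The synthetic generator

`generate_cohort()` and its companions produce every input the pipeline
consumes, with the structure the analysis assumes: haematocrit normal
(mean 0.42, SD 0.05) truncated to [0.25, 0.55]; partition coefficients
1.57 (parent) and 0 (metabolite); multiplicative lognormal measurement
error parameterized by CV (default 5%), chosen because the QC tables show
near-constant CV% across three orders of concentration; calibration lines
0.1683/−0.0012 and 1.1243/0.0124 response ratio per µg/mL with 2%
between-lot slope RSD; trough MPR lognormal with median 0.32 and log-SD
0.45; doses from {100, 200, 250, 300, 400} mg/day. The dose–concentration
link is deliberately minimal — steady-state trough = dose / apparent
clearance, clearance lognormal with median 52 L/day and 40% CV (typical
adult lamotrigine values, placing troughs in the 2.5–15 µg/mL reference
range), peak = trough × Uniform(1.3, 1.8) — because MPR screening needs
realistic magnitudes and between-subject spread, not a full PK model.
Clearance-shift outliers are injected by multiplying a subject's MPR by a
fold-change after the population draw, so an induced subject's ratio is
exactly `fold` times its pre-injection value.

What the generator does *not* emulate: chromatographic peak shapes,
carryover, drift and batch effects, additive noise floors near the LLOQ
(an `additive_floor` term exists, default 0), correlation between the two
analytes' assay errors, and within-subject PK nonstationarity. Passing
tests therefore demonstrate that the estimators are correct under the
stated error model, not that real patient data will meet the same
acceptance bounds.

Each generator stage reseeds deterministically from the master seed plus a
fixed offset (cohort +0, paired +1, calibration +2, QC +3), so stages are
individually reproducible and mutually independent, and the whole pipeline
is a pure function of (inputs, config, seed).

## Numerical and design choices

* Scalar bracketed minimization for $K$ (deterministic, no starting
  value); the fitted $K$ is verified in tests to be a local minimum
  against ±10⁻³ and ±10⁻² perturbations.
* Weighted-Deming weights are fixed at $1/\bar m_i^2$ from the observed
  pairs rather than re-estimated from fitted values; with proportional
  error the two differ negligibly and the fixed form is reproducible.
* Degenerate inputs fail loudly: zero variance in both Deming variables,
  haematocrit 1 with $K = 0$, zero fresh concentration in stability
  ratios, non-positive parent concentration in an MPR, duplicate subject
  ids in a cohort.
* Simulation sizes in the test suite (100-subject cohorts, 500-seed
  coverage loops) were chosen to bound the Monte-Carlo standard error of
  a 90% coverage check near 1% while keeping the default suite around
  half a minute.

## Known limitations

Venous-blood DBS only (capillary self-sampling adds a matrix difference
the model does not capture); scalar, concentration-independent $K$ per
analyte; pooled timepoints treated as independent in the regressions; no
pharmacogenetic interpretation of flagged subjects; and the plasma assay
enters only as a measured comparator column, never as a modelled
instrument.
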