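---
title: "Methods: schema validation, subphenotyping, and federated model evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: schema validation, subphenotyping, and federated model evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clifr)
```

This vignette is the package's account of its methods: what each stage
assumes, which tunable parameters matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical conventions adopted where a choice was genuinely open.

## The data model and its validation

CLIF organizes ICU EHR data into longitudinal tables linked by
`patient_id` and `hospitalization_id`. The unit of analysis is the
*encounter* (one hospital stay); an *ICU admission* is an ADT segment whose
`location_category` is `icu`. Standardized elements carry the `_category`
suffix and a closed set of permissible values; the paired `_name` column
preserves the source label verbatim so that mappings remain auditable. The
package commits to three conventions:

- **Categories are lower_snake_case and compared case-insensitively.** Site
  exports differ in capitalization; deterministic folding removes a whole
  class of spurious mismatch without touching `_name` fields.
- **All datetimes are stored timezone-aware in UTC** and converted on load.
  Multi-site data crosses time zones; any local-time convention breaks
  ordering checks at DST transitions.
- **Parquet is the canonical file format** (typed, compact); CSV (RFC 4180,
  UTF-8, ISO-8601 datetimes) is accepted for interchange. Unparseable
  datetimes become missing *and are counted*; a per-column failure fraction
  above `max_failure_fraction` (default 5%) aborts the load, because a
  systematically misparsed column is a schema problem, not noise.

Field-level schemas are fully specified for the tables the bundled analyses
consume (patient, hospitalization, adt, vitals, labs, respiratory_support,
medication_admin_continuous, scores); the remaining tables of the
entity-relationship model receive minimal schemas (keys, an event datetime,
a `_name`/`_category` pair) and the registry is extensible, since their full
column lists are site-specific. The validator reports violations as *data*
(table, row locator, rule, message) rather than exceptions: a site needs the
complete list, not the first failure.

## Synthetic data: what it emulates, and what it does not

`generate_dataset()` produces a CLIF-conformant multi-site ICU dataset with
complete ground truth. Its defaults are the package's reference study
conditions and are not adjusted per analysis:

- **Demographics**: age ~ Normal(60.6, 17.2) years, 45% female, race mix
  (59% White, 30% Black, 3.6% Asian, 8.1% other), 7% Hispanic — the
  characteristics of a large multi-site adult ICU population.
- **Timing**: hospital-admission-to-ICU offset ~ Exponential(mean 12 h);
  ICU length of stay ~ LogNormal(median 72 h, sdlog 0.8). Both tails are
  deliberately left untruncated so the cohort filters (48 h offset, 24 h
  stay) have real work to do, and ages below 18 occur at their natural
  Normal-tail rate.
- **Temperature subphenotypes**: mixture weights NT 0.57, HT 0.24,
  HFR 0.07, HSR 0.12 — midpoints of the prevalence ranges reported across
  sites, normalized; the midpoint choice is arbitrary within those ranges
  and is flagged as such. Each encounter's hourly temperatures are its
  label's reference curve plus i.i.d. Gaussian noise (SD 0.3 °C by
  default; measurement-level temperature noise of ±0.3 °C is typical of
  charted core temperatures).
- **Outcomes**: in-hospital death follows a logistic model on age
  (+0.045/year), latent albumin (−1.6 per g/dL) and subphenotype (log-odds
  0, 0.6, 0.3, log 2 for NT, HT, HFR, HSR); the intercept is solved
  numerically so the marginal prevalence equals the 9.5% target. These
  coefficients give the true-probability model an AUC of ≈0.79, matching
  the discrimination a well-specified ICU severity model attains in
  practice, and make HSR-vs-NT odds-ratio recovery well-posed with a known
  truth of 2.0. Ventilation follows the same construction at 38%
  prevalence, concentrated in the hyperthermic subphenotypes.
- **Missingness and mess**: labs arrive as one admission panel plus
  Poisson-thinned repeats (1.5/analyte/day); a configurable fraction of
  encounters (default 0.07%) has no temperatures at all; a configurable
  fraction of vitals/labs values (default 0) is replaced by values outside
  the plausibility ranges and logged row-by-row, making outlier cleaning
  exactly auditable; roughly 10% of ICU stays are recorded as two ADT
  segments separated by a sub-hour gap, the transfer artifact the cohort
  logic must merge.

What the generator does **not** emulate: inter-site coding idiosyncrasies
(all `_name` strings are clean), informative missingness (labs are thinned
at random, not by acuity), carry-forward charting, within-encounter
correlation beyond the subphenotype curve, pharmacology, or readmission
structure. Tests passing on synthetic data therefore demonstrate
*correctness of the machinery* — schema conformance, exact bookkeeping,
estimator behavior under known truth — not performance on real EHR data,
where coding noise and informative missingness dominate.

## Cohort discovery and outlier handling

An encounter qualifies if age at admission ≥ 18 years, the first ICU ADT
segment begins ≤ 48 h after the hospital admission datetime, contiguous ICU
time from first ICU entry is ≥ 24 h, and the admission date falls in the
study window. Three conventions were open and are fixed as follows:

- **Boundaries are inclusive** ("within 48 hours", "at least 24 hours",
  "≥ 18 years").
- **Contiguity**: back-to-back ICU segments separated by less than 1 h are
  merged before measuring the stay, and the stay is the span of the first
  merged block. Sub-hour gaps are transfer artifacts; a genuine ward
  transfer and ICU readmission should not be concatenated.
- **Window membership is by hospital admission date**, not ICU entry, since
  the study window modifies admission.

Outlier handling never deletes rows: values outside the per-category
plausibility range are set to missing and counted per (stream, category).
The shipped ranges are package defaults (documented in
`default_outlier_ranges()`), fully overridable, since the consortium's own
table is not public. The operation is idempotent and preserves record
counts, which the tests assert exactly against the generator's injection
log.

## First-24-hour features and the mortality model

Features are min/max/mean aggregates over the half-open window
`[icu_entry, icu_entry + 24 h)` — half-open so a measurement exactly at
24 h belongs to the next window and is never double-counted. Encounters
with no observation for a feature get a missing value; nothing is imputed.
The default specification carries the five headline predictors (minimum
albumin, maximum and mean AST, minimum pulse, minimum DBP) plus ten common
vitals/labs aggregates as a documented placeholder; the production
30-predictor list is configuration, not code.

The classifier backend is xgboost, selected because gradient-boosted trees
handle missing values natively — the stated reason for the model family —
and the backend sits behind a thin interface (matrix in, probabilities
out, JSON text export) so another boosting library can be substituted. The
default grid (learning rate 0.05/0.1, depth 2/3, 120 rounds, minimum child
weight 5) is deliberately conservative: at ICU mortality prevalence
(~10%), cohorts of a few thousand encounters contain only hundreds of
events, and an aggressive grid (depth 4, learning rate 0.3) measurably
overfits — on held-out synthetic data it scored below a plain logistic
benchmark, while the conservative grid beats it. Grid choice is by mean
5-fold cross-validated AUC with seeded fold assignment; everything is
deterministic given the seed.

## Temperature standardization and min-MSE classification

Temperatures recorded in `[icu_entry, icu_entry + 72 h]` are binned to
integer hours by the within-hour mean; Fahrenheit-labelled values are
converted with C = (F − 32) × 5/9 first. "Sum of mean squared errors"
against a reference curve is implemented as the **mean** squared error over
the encounter's *observed* hours: dividing by the observed-hour count makes
the criterion scale-free across encounters with different observation
density, so a sparsely measured patient is not penalized for missingness.
(For a fixed encounter the argmin is unchanged by this normalization; it
matters only if raw sums were ever compared across encounters.) Ties break
by the fixed label order NT < HT < HFR < HSR. The minimum-observation
threshold is 1: only encounters with no temperatures at all are excluded,
and those exclusions are recorded with a reason.

The bundled reference curves are **synthetic stand-ins**, parameterized as
start/plateau/resolution-half-life exponentials with the qualitative shapes
the labels imply (NT flat at 37.0 °C; HT starting 36.2 °C and staying below
NT; HFR starting 38.6 °C with a 6 h half-life; HSR starting 38.6 °C with a
30 h half-life). They are *not* the published group-based-trajectory-model
curves, which are not printed anywhere reusable; every classifier entry
point accepts an externally supplied `hour, NT, HT, HFR, HSR` CSV, and
matching is on the hourly grid (whether the original validation matched on
raw hours or on polynomial evaluations is unstated; the hourly grid is this
package's documented choice). Re-estimating the trajectory model itself is
out of scope.

Adjusted outcome models are logistic regressions of mortality or
ventilation on subphenotype indicators (NT reference) plus age
(continuous), sex, race, and ethnicity (categorical, using the
Asian/Black/White/Others and Hispanic/Not-Hispanic sets), fitted by IRLS to
tolerance 1e-8. Separation on the subphenotype contrasts is reported as a
fit failure rather than silent divergent output; sparse *covariate* cells
(e.g. zero deaths among a small race stratum) merely yield wide intervals,
which is ordinary behavior, not failure.

## Evaluation suite

- **AUC**: the rank-based Mann–Whitney estimator, ties counted ½.
- **AUC interval**: DeLong's analytic variance from placement values, 95%
  Wald interval truncated to [0, 1]; degenerate variance (e.g. perfect
  separation) returns the widest valid interval with a warning rather than
  a zero-width one. A seeded bootstrap is not provided because the analytic
  interval is standard and testable; the CI method was an open choice.
- **Brier score**: mean squared error of predicted probability.
- **Calibration**: equal-count bins (deciles by default) of predicted risk
  with mean predicted vs observed rate; equal-count rather than
  equal-width because at low prevalence equal-width bins starve the upper
  range.
- **Decision curves**: positivity is `score ≥ threshold` (closed on the
  left, a fixed documented convention); each report always includes the
  0.3 high-risk threshold with model, treat-all, and treat-none arms.

The federated unit is `evaluate_site()`: each site runs the same function
on the shared model object and its local data, and exchanges only the JSON
report (serialized at 17 significant digits so round-trips are lossless).
Aggregation of per-site summaries sums counts and recomputes percentages
from combined numerators and denominators; the combined age SD is the
pooled between+within approximation from per-site (n, mean, SD), documented
as approximate because no exact method exists given only site moments.
Rendered percentages use two significant figures below 10% and integers
otherwise — the one consistent rule that reproduces the bundled reference
consortium table's combined column almost everywhere (two of its cells,
7.0% and 8%, are mutually inconsistent with any single rounding rule; the
renderer follows the rule, not the cells).

## Problem sizes used by the test suite

The suite exercises the full pipeline at deliberately modest scales chosen
as the smallest that make each statistical assertion sharp: 300-encounter
datasets for exact bookkeeping checks, 2,000 encounters for model-signal
checks, 1,000 encounters (73 observed hours each) for ≥95% subphenotype
recovery at 0.2 °C noise, 500 simulations for DeLong coverage, and 20,000
encounters for odds-ratio recovery within three standard errors. Those
sizes are statements about statistical resolution, not limits of the
implementation: generation is vectorized and scales linearly in rows.

## Known limitations

- The registry ships 22 uniquely named tables; the entity-relationship
  diagram's own list names one table twice, so the identity of the last
  table is ambiguous — the registry is extensible precisely so either
  reading works.
- `dataset_summary()` takes hospital counts from distinct `hospital_id`
  values in ADT, which undercounts if a site omits that optional column
  (it then reports 1).
- The adjusted models use complete cases for covariates; real sites with
  missing demographics need an explicit missing-category policy first.
- Synthetic-data realism limits are listed above; in particular, the
  bundled reference trajectories are stand-ins, and mortality-model
  performance numbers on synthetic data say nothing about performance on
  any real population.
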