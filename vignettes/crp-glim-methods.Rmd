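---
title: "Maximum CRP over the first three ICU days as a GLIM inflammation criterion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum CRP over the first three ICU days as a GLIM inflammation criterion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glimcrp)
```

## The clinical question

The GLIM framework diagnoses malnutrition from a phenotypic criterion (here:
low BMI, with Asian age-dependent thresholds of < 18.5 kg/m² under 70 years
and < 20 kg/m² at 70 years and older) combined with an etiologic criterion
reflecting disease burden or inflammation. For critically ill patients no
consensus inflammation criterion exists. C-reactive protein (CRP) is cheap
and near-universally measured, but it is a lagging marker: it starts rising
4–6 h after an insult and peaks only around 36 h. A CRP drawn on the day of
ICU admission can therefore miss inflammation that a measurement on day 1 or
2 would catch — and initial nutritional assessment guidelines allow a 48-h
window, so using the *maximum* CRP over hospital days 0–2 is clinically
admissible.

`glimcrp` implements the full analysis that evaluates this idea on an
admission-level claims cohort:

1. eligibility filtering and ICD-10 diagnosis categorisation,
2. a claims-adapted SOFA severity score and a catecholamine index,
3. linear interpolation of sparse CRP trajectories and the three windowed
   CRP statistics (day 0, max days 0–1, max days 0–2),
4. ROC analysis of each statistic against a composite poor-outcome endpoint,
   with Youden-index cut-off selection overall and per diagnosis subgroup,
5. four-group GLIM classification (CRP± × BMI±) and rank-based outcome
   comparison (Kruskal–Wallis omnibus, Conover–Iman pairwise post hoc).

Because the kind of administrative claims data this analysis targets is
proprietary, the package ships a synthetic cohort generator that plays the
role of the data source and doubles as the test bed: every claim the test
suite makes about the pipeline is demonstrated on cohorts with *planted*,
known effects.

## The composite outcome

Each admission contributes three binary poor-outcome indicators:
in-hospital death, Barthel index (BI) < 60 at discharge (substantial
dependence in activities of daily living), and length of hospital stay
(LOS) ≥ 14 days. The primary endpoint is their union (the composite).
Secondary endpoints are death by day 14, death by day 28, and BI and LOS as
continuous values. BI uses a strict `<` and LOS an inclusive `≥`, and the
composite is monotone in its components by construction.

## CRP handling

CRP is recorded per hospital day (day 0 = admission day) on days 0–6, in
mg/dL. Missing values on days 0–2 are filled by linear interpolation between
the nearest observed measurements anywhere in days 0–6; a gap before the
first observation or after the last takes the nearest observed value (flat
carry — the degenerate case of linear interpolation, chosen over inventing a
slope). Observed values are never altered. Patients with CRP actually
measured on all of days 0, 1 and 2 form the *complete-case* population; the
*all-case* population additionally contains the interpolated patients.
Interpolation is exact on any linear trajectory and never overshoots its
bracketing observations; both properties are enforced by tests.

## ROC analysis and cut-off selection

For each analysis population × CRP window × diagnosis subgroup
(all + 8 categories; 54 combinations) the package builds an ROC curve for
the composite outcome. Conventions, fixed once and tested:

* thresholds are the distinct observed score values, swept in descending
  order, with `score ≥ threshold` counted as a positive call; a sentinel
  above the maximum contributes the (0, 1) corner. Observed values (rather
  than midpoints) are used so that reported cut-offs are actual measurement
  values;
* AUC is the trapezoidal area, which the suite verifies to be identical
  (within 1e-12) to the pair-counting form — the probability that a random
  positive outscores a random negative, ties counted ½ — and to agree with
  pROC;
* the optimal cut-off maximises the Youden index J = sensitivity +
  specificity − 1 over observed thresholds, ties broken toward the
  *smaller* cut-off (favouring sensitivity in a screening context); within
  each population × subgroup the cut-off is reported only for the window
  with the highest AUC, which is how the corresponding summary tables are
  conventionally constructed;
* no confidence intervals are attached to AUCs.

Four-group classification then uses CRP+ ⇔ max CRP days 0–2 strictly above
the cut-off. Strict `>` follows the explicit statement of the
classification rule in the literature this analysis follows; patients
exactly at the cut-off are CRP−. By default the pipeline classifies with
the Youden cut-off of the all-case, all-diagnoses, days 0–2 window; a fixed
cut-off (e.g. 3.82 mg/dL) can be supplied instead.

## Severity scoring from claims data

Claims databases lack PaO2/FiO2, so the respiratory SOFA component is scored
from the recorded level of respiratory support (none 0, oxygen 1, NPPV/HFNC
2, invasive ventilation 3, ECMO 4). The cardiovascular component scores 0
for any patient on no catecholamines — regardless of blood pressure, which
claims data also lack — and uses the standard SOFA dose bands otherwise.
The four laboratory components (coagulation, liver, renal, CNS) are inputs:
no laboratory thresholds are assumed, and the generator emits these
subscores directly. The catecholamine index summarises day-1 vasoactive
load as dopamine + dobutamine + 100 × noradrenaline + 100 × adrenaline
(all μg/kg/min).

## Rank-based group comparison

All eight outcomes — binary and continuous alike — are compared across the
four groups with the Kruskal–Wallis test (tie-corrected, χ² approximation;
delegated to `stats::kruskal.test`) followed by the Conover–Iman all-pairs
post hoc. The Conover statistic uses pooled mid-ranks, the tie-corrected
pooled rank variance, and the Kruskal–Wallis-corrected variance factor
(N − 1 − H)/(N − k), referred to a t distribution with N − k degrees of
freedom. The H-corrected variant was chosen and is documented here because
the variant is rarely stated explicitly in applied papers; a permutation
study in the test suite confirms its raw p-values are uniform under the
null. Raw and Bonferroni-adjusted (× k(k−1)/2) p-values are both reported —
an all-pairs comparison of 4 groups runs 6 tests per outcome, and published
analyses in this area appear to have judged significance on an adjusted
scale (declaring p = 0.04 non-significant) without saying so; the
significance level applied to adjusted p-values is a configuration knob
(default α = 0.05).

## The synthetic cohort generator

`simulate_cohort()` emulates the admission-level schema of a Japanese
DPC-style claims extract. Its defaults are the study conditions; they were
fixed from the published marginals of the cohort this analysis models and
are not tuning knobs:

* demographics: age ~ truncated normal (mean 73, SD 14.5 years), 58.8%
  male, BMI ~ truncated normal (mean 22.5, SD 4.6 kg/m²);
* diagnosis mix: neurology-heavy (27.5% neurology, 24.6% cardiovascular,
  11.4% sepsis, …);
* CRP kinetics: per category, log-scale day-0 baseline with patient-level
  spread, piecewise log-linear rise to a peak at day 1.5 (the ~36-h CRP
  peak), then exponential decay, with independent day-level log-normal
  noise (SD 0.35). Sepsis and digestive admissions present with high day-0
  CRP; neurology presents low;
* missingness: independent Bernoulli per day, day-specific probabilities
  (0.15 on day 0, 0.38 on days 1–2, 0.45–0.5 later) chosen so that roughly
  a third of admissions are complete cases. The generator deliberately does
  *not* model informative measurement (sicker patients measured more),
  because no missingness mechanism is documented for the source data — a
  stated limitation of what passing tests show about real data;
* outcomes: each of death, BI < 60 and LOS ≥ 14 is drawn from a logistic
  model whose covariates are the *true, pre-censoring* maximum CRP over
  days 0–2 (per mg/dL), the low-BMI flag and age (per decade over 70).
  Using the uncensored maximum plants a known signal that interpolation
  can only partially recover — exactly the situation the windowed-AUC
  comparison probes. Default coefficients give overall rates of roughly
  15% death, 51% BI < 60, 77% LOS ≥ 14, and a Youden cut-off of 4–5 mg/dL;
* consistency fill-ins: LOS is drawn conditional on the LOS ≥ 14 flag,
  death day geometric truncated at LOS, BI discretised to 0–100 in steps
  of 5 from a latent normal on the side of 60 dictated by its flag, and
  interventions/SOFA subscores are tilted toward high-CRP patients through
  a single severity link so that CRP+ groups look sicker, as real tables
  do;
* a 5% fraction of records violates exactly one eligibility rule (minors,
  short stays, missing BI/BMI, no CRP at all, non-emergent admission) so
  the filter and attrition report are exercised end to end.

`planted_truth()` exposes the generation-time coefficients and per-patient
uncensored maxima for parameter-recovery tests. Everything is deterministic
given the spec (which contains the seed), and the generator restores the
caller's RNG state.

What the generator does **not** emulate: raw claim message formats,
per-prescription dosing records, informative CRP measurement, correlated
multi-morbidity codes, or center effects. Quantitative results that depend
on the real data's covariance structure — the published AUC of 0.65 or the
3.82 mg/dL cut-off — are therefore reproduced only qualitatively
(orderings, gradients, magnitudes), never asserted numerically.

## Numerical and degenerate-input choices

* ROC construction refuses single-class outcomes (`degenerate outcome`);
  the subgroup sweep instead marks such cells undefined (NA) so a small
  stratum cannot crash a report.
* Youden ties (equal J at several thresholds, within 1e-12) resolve to the
  smallest cut-off.
* A CRP series with a single observed day fills days 0–2 flat at that
  value; a series with no observations is an upstream eligibility
  exclusion and an error at the interpolation layer.
* Conover's variance factor (N − 1 − H)/(N − k) is floored at 0 (attainable
  only with pathological tie structures), giving p = 0 for infinitely
  separated groups rather than NaN.
* In the eight-category ICD-10 mapping, a sepsis code dominates everything;
  otherwise the first code in record order decides, with the narrower
  neurology range I60–69 tested before the enclosing cardiovascular range
  I00–99. Matching uses the three-character prefix.
* Eligibility rules never short-circuit: every failing reason is recorded,
  in a fixed order, so attrition counts are reproducible.

## Problem sizes used in validation

The planted-effect and calibration checks run at n = 20 000 admissions
(window-ordering check averaged over five seeds; null-AUC recovery within
0.5 ± 0.02; marginal calibration within three standard errors), the
permutation study of Conover calibration uses 2000 permutations of 30
observations, and the AUC/Youden property tests use 200 random instances of
up to 50 observations each. These sizes give comfortable statistical
resolution for every ordering and calibration claim while keeping the whole
suite fast.

## Known limitations

* The four-group outcome contrasts inherit whatever confounding the
  severity link plants; the pipeline deliberately performs no regression
  adjustment, mirroring the descriptive design it implements.
* "Emergent ICU admission" is an input flag; claims-level admission-type
  semantics are out of scope.
* The sepsis ICD-10 code list is an input flag, not re-derived.
* Whether day counting for "3 consecutive ICU days" includes day 0 is
  delegated to the input (`icu_consecutive_days ≥ 3` is applied as given).
* LOS ≥ 14 percentages in this package's tables use the full group size as
  denominator; reference tables in the literature can instead condition on
  14-day survival, which is why the reference-count fixture used in the
  test suite records each printed row's denominator explicitly.
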