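---
title: "Evaluating transdermal fentanyl use in claims data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating transdermal fentanyl use in claims data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftduse)
```

## The problem

Fentanyl transdermal patches (FTD) are extended-release opioids used for
chronic moderate-to-severe pain; each patch releases drug over 72 hours.
National insurance claims record every dispensed item — patient, date,
institution, drug, strength, quantity — which makes them the natural
substrate for asking whether FTD prescribing in non-cancer outpatients
stays within safe-use recommendations. `ftduse` implements that analysis
as a reusable, fully tested pipeline: dose standardization, a
per-patient-year rule engine, utilization-trend statistics, and an
inequality assessment of how FTD consumption is distributed across
patients.

Because national claims databases are not publicly shareable, the package
ships a synthetic claims generator whose output has the same structure and
carries ground-truth labels. Everything downstream is validated against
those labels.

## Cohort construction

The analysis unit is the **patient-calendar-year**: one patient may
contribute several years, each judged independently, mirroring yearly
cross-sectional claim samples. A patient-year enters the cohort iff

1. it contains at least one outpatient, FTD-containing reimbursement;
2. the recorded age is 20 or more; and
3. no diagnosis code that year starts with "C" (the ICD-10 malignant
   neoplasm chapter), in any position and any care setting.

Exclusion is per year, not per patient: a cancer code in 2015 removes the
2015 patient-year only. D-chapter codes (benign and in-situ neoplasms) are
retained — "C" is the conservative, standard malignancy chapter. Age is
taken as recorded; no birthday arithmetic is attempted.

A **reimbursement** groups all claim lines sharing patient, visit date and
institution — the claims notion of one prescription event. Claims data do
not define this aggregation explicitly; same-day, same-institution lines
are one visit, which is also what the interval-based dose estimate (below)
assumes. Only FTD-containing outpatient reimbursements enter the rule
engine; oral opioids dispensed at the same visit stay attached to it,
opioid-only visits are dropped.

## Dose standardization

All doses are unified to morphine milligram equivalents (MME). One patch
of strength $s$ mcg/h contributes $s \times 2.4 \times 3$ MME (conversion
factor 2.4 per mcg/h per day; approved use period 3 days per patch), so an
FTD item of $q$ patches carries $q \cdot s \cdot 7.2$ MME over $3q$
covered days. The covered FTD duration is always derived as patches
$\times$ 3 — never taken from a days-supplied field. Oral co-opioids
contribute strength (mg) $\times$ quantity $\times$ a per-drug factor over
their dispensed days; the factors default to the CDC oral conversion
factors (morphine 1, oxycodone 1.5, hydrocodone 1, hydromorphone 4,
tramadol 0.1, codeine 0.15) and are configuration data, replaceable via a
`drug_code,factor_mme_per_mg` file.

Two per-reimbursement dose measures:

* **MME/day** — total MME divided by the *longest* prescribed duration
  among the reimbursement's items. The FTD's own implied duration counts
  toward that maximum: the patch is itself one of the prescribed opioids
  and usually sets the duration.
* **eMME/day** — total MME divided by the interval to the patient's next
  visit, under the assumption that everything dispensed is consumed before
  returning. Early revisits push eMME/day above MME/day, late ones below.

Two conventions needed a decision. First, the final reimbursement of a
year has no next visit; it uses its own longest duration as the interval,
which preserves the identity *eMME/day = MME/day for a fully adherent
patient* exactly (the test suite asserts it to the last bit). Second,
same-day visits at two institutions give a zero interval; the divisor is
clamped to 1 day and the clamp count is reported, rather than discarding
the visit or propagating an infinity. eMME always uses the raw
inter-visit interval: the 3-day early-revisit allowance belongs to the
overlap criterion, not to dose.

## The rule engine

Patient-years are grouped by age — working age (<65) vs older adult
(≥65) — and by prescription frequency: single-prescription patients are
evaluated on 2 criteria, multiple-prescription patients on 5. All
thresholds are boundary-inclusive ("≤ compliant, > flagged"): the
criterion wording "90 days or less (30 patches or less)" fixes the
convention, and every synthetic archetype keeps a guard margin so the
boundary never decides a label.

* **Period** — any single prescription > 90 FTD days (31+ patches).
  Consecutive prescriptions never combine: a year of back-to-back 30-patch
  prescriptions is compliant, on the reasoning that each re-prescription
  is a fresh clinical decision.
* **Dose** — single: MME/day > 90; multiple: *any* reimbursement with
  eMME/day > 90. The any-visit reading is the stricter interpretation and
  matches the per-reimbursement definition of eMME/day.
* **Per-prescription overlap** — for consecutive visits $i, i{+}1$:
  $\max(0, \text{FTD days}_i - (\text{date}_{i+1} - \text{date}_i)) > 3$.
  Only FTD durations cover the interval; co-opioid supplies do not extend
  it, since the criteria govern FTD use.
* **Annual overlap** — total pairwise overlap above the allowance:
  $\min(0.16 P, 30)$ days for an annual prescription period $P < 182$
  days (first to last visit), a fixed 30 days for $P \ge 182$. $P = 182$
  exactly falls in the fixed branch. Raw overlaps are summed — the 3-day
  per-prescription allowance does not subtract from the total, because the
  16%/30-day budget is what absorbs routine early revisits.
* **Multi-institution** — more than 3 distinct institutions among the
  year's FTD reimbursements. Non-FTD opioid visits do not count toward
  it.

A verdict of potentially inappropriate ("I") follows from any failed
applicable criterion. For single-prescription patients the three
inapplicable flags are reported as missing, not `FALSE` — they were never
evaluated. Increasing any reimbursement's patch count can only turn flags
on, never off; the suite checks this monotonicity.

## The synthetic generator

`generate_cohort()` emulates the structure of yearly claim samples:
patient-years with sex and age, ICD-10-coded diagnoses drawn from the
chapters prominent in non-cancer pain claims (musculoskeletal, injury,
nervous, digestive, circulatory), 12–100 mcg/h patch strengths, optional
oxycodone co-prescriptions, visit-interval jitter, and an institution
pool. All randomness flows from one seed; the same seed gives
byte-identical output.

Violations are planted one criterion per archetype so a recovery failure
localizes to a rule: `long_period` (31–35 patches), `high_dose_single` /
`high_dose_multiple` (50+ mcg/h ⇒ 120+ MME/day or eMME/day on an otherwise
on-schedule calendar), `early_revisit_overlap` (one 25-day revisit within
30-day supplies: overlap 5 > 3 while the annual budget stays intact),
`chronic_annual_overlap` (twelve 27-day revisits: each overlap exactly 3,
total 33 > 30), `doctor_shopping` (4–5 distinct institutions), plus
`mixed_violations` with four simultaneous failures. Three decoy archetypes
(cancer-coded, pediatric, inpatient-only) must be removed by the cohort
filters. Every archetype holds its defining inequality with a margin of at
least 1 day or 5 MME/day, so integer jitter cannot flip a label. Compliant
multi-visit patients draw all visits from at most 2 institutions, one
under the limit.

The default mix generates 1020 eligible patient-years plus 80 decoys
across 2014–2020 — large enough to populate all eight groups yearly,
small enough that the full label-recovery suite runs in seconds. The
generator reproduces the *structure* the pipeline assumes, not the joint
distribution of real prescribing: doses and intervals are drawn from small
discrete sets, diagnoses are independent of dose, and there is no
within-patient correlation across years. Passing tests therefore certify
the pipeline's logic, not any claim about real-world prevalence.

## Trends and inequality

Yearly summaries report patients and reimbursements per 100,000
registrants, sex/age-stratified rates, and means with SDs of
reimbursements per patient and annual FTD MME. The annual percent change
of a rate series is the log-linear APC: OLS of $\log(\text{rate})$ on
calendar year, $\mathrm{APC} = 100(e^{\hat\beta} - 1)$. Among candidate
APC definitions, the log-linear fit is the one consistent with the full
seven-year published rate series (an endpoint-only geometric change is
not), and it returns exactly $100(r-1)$ on a geometric series.

Inequality of FTD use is assessed on patient-level annual FTD MME, pooled
across years within each age stratum (pooling, rather than averaging
yearly coefficients, matches a single published coefficient per stratum).
The Gini coefficient uses the mean-absolute-difference form
$G = \sum_{ij} |x_i - x_j| / (2 n^2 \mu)$, computed through its sorted-rank
identity; tests verify agreement with both a brute-force $O(n^2)$ oracle
and the Lorenz-trapezoid estimator to $10^{-9}$, and the degenerate
equal-usage case returns exactly 0. The **modified Lorenz curve** ranks a
subgroup's patients by usage in *descending* order (ties broken by patient
id) and plots, at top-fraction $f \in \{0.01, \dots, 1\}$, the share of
the *parent age stratum's* total FTD MME held by the subgroup's top
$\lceil f n \rceil$ patients — so at $f = 1$ subgroup curves of a stratum
sum to 1 and the curves are directly comparable across subgroups.
Within-group normalization is available as an option. Percentile counts
use the ceiling, with no interpolation between patients.

Report tables round to one decimal, half away from zero; internal
computation is never rounded. Significance testing between groups
(ANOVA/Tukey, Kruskal–Wallis/Dunn, chi-square) is left to the standard R
routines on the exported tables and is deliberately not wrapped.

## Numerical and degenerate cases

* Zero inter-visit intervals clamp to 1 day (logged).
* An unknown opioid code fails loudly, naming the code.
* A claims table with no eligible patient-years is an error, not an empty
  report.
* `gini()` rejects all-zero and length-1 input; the equal-usage case
  short-circuits to exact 0.
* Thresholds are configurable (`criteria_thresholds()`, YAML overrides)
  but validated positive; defaults reproduce the published criteria, so a
  bare run is the reference analysis.

## Known limitations

Claims record dispensing, not consumption: adherence is invisible, which
is precisely why eMME/day exists as an estimate. The per-year cancer
exclusion cannot see a cancer history recorded outside the analyzed year.
The generator's independence assumptions (above) mean recovery rates on
synthetic data say nothing about clinical prevalence in any real
population, and patients judged by clinicians to need high doses or long
courses will be flagged by these purely prescriptive criteria.
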