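---
title: "Methods: the PIVAS quality-control scoring engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PIVAS quality-control scoring engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pivasqc)
```

## The problem

Pharmacy Intravenous Admixture Services (PIVAS) are hospital units that
centrally compound intravenous medications under clean-room conditions.
Regional health administrations assess them with a standardized quarterly
report — 67 data items covering basic information, hardware, personnel,
work efficiency, infection control and informatics — and a composite
evaluation matrix of 20 indicators that converts those raw items into
points across five categories with a total of 100. `pivasqc` implements
that assessment chain as a reusable, testable engine: schema validation
and audit, rubric scoring, regional benchmarking, and longitudinal
comparison, plus a synthetic cohort generator so the entire pipeline can
be exercised without access to any real hospital's reports.

## The submission schema and audit model

A submission is one facility-quarter: a typed record over the item
identifiers `A01`–`F03` (12/12/10/19/11/3 items per aspect, 67 in all).
Types are declared per item (counts, areas in m², percentages,
categorical strings, flags) and coercion failures are parse errors naming
the item. Validity is then an *audit*, not an exception: rules emit
findings with `error` or `warning` severity and a submission fails
exactly when an error-severity finding exists. Beyond completeness and
range checks, the audit enforces the cross-field identities implied by
the data dictionary: flagged unreasonable prescriptions cannot exceed
total prescriptions (`D06 ≤ D14`), physician-modified prescriptions
cannot exceed flagged ones (`D17 ≤ D06`), beds served by the unit cannot
exceed the hospital's beds (`B10 ≤ B02`), and the reported
unreasonable-prescription proportion `D16` must agree with
`100·D06/D14` within 0.5 percentage points (a redundancy check; the
engine also recomputes `D16` when yearly aggregates are formed).
Trained-headcount overruns are warnings, since headcounts may change
within a quarter.

Items required for scoring are exactly those consumed by some indicator
or audit rule; purely administrative contact items are optional. Two bed
items (`B04`, `B11`) have an ambiguous relation to the beds-served count
`B10` in the source dictionary and are recorded but unscored.

Quarterly records aggregate to facility-years by summing period counts,
averaging daily-average and rate items, and carrying stocks and
categories forward; frequency thresholds (cleaning, filter maintenance)
scale with the number of quarters covered, so a record scores identically
whether presented as four quarters or one yearly aggregate.

## The evaluation matrix

Twenty indicators in five categories (hardware 11, personnel 14, work
efficiency 49, infection control 13, information 13). Each indicator is
an ordered branch table over derived metrics — average daily deployment
`D05+D15`, console capacity `B05+B08+B12`, training sessions per trainee
`(C02+C07)/(C03+C08)`, pharmacist proportion `C10/(C10+C06)`, infusions
per bed `D10/B10`, infusion groups per syringe `D01/D09`,
temporary-order rate `D15/D05`, disposition rate `D17/D06`, error rate
`(D08+D18+D19)/D01` — with the first matching branch awarding points.
Boundary conventions are taken literally from the scoring text: strict
`>` where it says "more/higher than", the closed interval on the
alternative branch.

Several places in the printed matrix are under-determined; the package
fixes them as its own documented conventions:

* **Working area.** The required area is 300 m² up to 2 000 bags/day,
  500 m² up to 3 000, then 650 m² plus 50 m² per further 500 bags
  (ceiling). Meeting the requirement earns 5 points, failing earns 0 —
  pass/fail indicators whose failure branch is unstated (working area,
  auxiliary area, console capacity, allocation per person) score 0 on
  failure, the conservative reading consistent with observed sub-maximal
  cohort means.
* **Infusion types** are scored additively (+3 parenteral nutrition,
  +3 anticancer, +2 antibiotics, +2 general), the only reading that can
  reach the printed maximum of 10.
* **Unreasonable prescriptions and disposition** has two printed
  branches with identical conditions but different points; the package
  uses the symmetric four-cell table (low rate/high disposition 5, both
  favorable-on-one-axis cells 3, high rate/low disposition 1).
* **Error control** reads "exceeds 30 % of the average" as *exceeds the
  average by 30 %*: below average 5, within 1.3× the average 3, beyond
  2. The numerator groups all three error items.
* **Informatics degree** awards +3 for an information system, +2 for a
  clinical-records system, and +min(3, number of automatic-equipment
  kinds), reaching the printed maximum of 8 at three kinds.
* **Tracing control** divides the count of traceability-capable
  equipment kinds (a configurable vocabulary flag; dispensing scanners,
  vertical-flow benches and similar) by console capacity; the printed
  numerator is a boolean flag, which cannot yield the printed graded
  thresholds.
* **Cleaning frequency** normalizes the per-quarter count to weeks
  (weekly ⇔ ≥ 13 per 13-week quarter, biweekly ⇔ ≥ 7, monthly ⇔ ≥ 3),
  scaled by the quarters covered.

Five branches compare against **regional reference averages** (daily
deployment, infusions per bed, groups per syringe, unreasonable and
disposition rates, error rate). These provincial values were never
published, so the reference is injectable configuration with provenance
tracking; `cohort_reference()` derives a cohort-mean fallback when no
configured value exists. The shipped defaults are the anchors of the
synthetic world below (1 500 bags/day, 6 infusions/bed, 3 groups/syringe,
1.5 % unreasonable rate, 0.8 disposition rate, 0.002 error rate).

**Undefined inputs** (missing items, zero denominators) are explicit
markers, never silent zeros. The default lenient policy scores the
affected indicator 0 and annotates the scorecard — real quarterly data
have gaps — while strict mode raises an error naming the indicator and
its inputs.

## Benchmarking and attainment

A regional benchmark is the exact per-indicator mean/max/min over a
cohort of scorecards (sample sd, n−1, for category subtotals and the
total), the numbers a facility sees beside its own scores. Radar
datasets normalize each axis by its indicator maximum to [0, 1].

The *attainment rate* expresses a mean indicator score as a percentage
of its maximum. Both a raw value and a display value are kept; the
display convention is one decimal place, snapping to an integer when the
raw percentage is within a quarter point of one — the resolution
implied by a mean printed to two decimals over a single-digit maximum.
That reproduces the platform's mixed reporting style (2.13/4 → 53 %,
1.67/5 → 33.4 %, 2.87/5 → 57.4 %).

## Longitudinal comparison

Yearly panel summaries are exact means and n−1 standard deviations per
indicator, category and total, with balanced-panel enforcement.
Normality screening uses Shapiro–Wilk with a constant-input guard.

For pairwise year comparisons the original platform analysis used a
generalized-estimating-equation fit in commercial software. The package
deliberately substitutes a **paired sign-flip permutation test** on the
within-facility differences: under the null of no year effect each
facility's difference is symmetric about zero, so all 2ⁿ sign patterns
of the observed differences are equally likely. The statistic is the
mean difference; the two-sided p-value is the fraction of patterns at
least as extreme (exact enumeration when 2ⁿ ≤ 2×10⁵ — always, for a
15-facility panel — otherwise seeded Monte-Carlo with the add-one
estimator, default 10⁵ draws). The choice is documented in every result
via a method tag. Rationale: for n = 15 non-normal bounded scores an
exact, assumption-light test is more transparent than re-implementing a
particular GEE flavor, and its type-I error is verified by simulation in
the acceptance suite. P-values are unadjusted like the platform's
reports; a Holm option exists, default off.

## The synthetic world

The generator emulates the platform's evaluation panel: 15 public
hospitals (> 500 beds) reporting quarterly for 3 years, with quality
improving and dispersion shrinking. Each facility draws a latent quality
`q ∈ [0, 1]` from a clamped normal with mean 0.55 and sd 0.17 — chosen
once to mirror a year-one total of roughly 55 ± 17 points — and each
year closes a fixed fraction (default 0.25) of its remaining gap to 1:
`q_y = 1 − (1 − q₁)(1 − drift)^(y−1)`. This one mechanism raises means
and shrinks dispersion jointly, the qualitative pattern of the observed
panel; `drift = 0` gives an exchangeable null panel used for
calibration.

Generation is **branch-first**: latent quality plus indicator-level
Gaussian jitter (default sd 0.10) picks a target branch on each
indicator's ladder, and the 67 raw items are back-solved so the rubric
lands exactly in those branches. Target values sit mid-branch, away from
thresholds, so integer rounding cannot flip a branch; the four quarterly
records of a facility-year are identical by construction, so yearly
aggregation preserves every branch; and cross-indicator couplings are
reconciled explicitly (console capacity pins the served-bed count;
traceable equipment kinds feed the informatics equipment count). Every
generated submission passes audit, and the generator records per
facility-year truth: the latent quality and the points each indicator
was generated to hit.

What a green test does and does not establish: the synthetic world is
*closed under the rubric* — its reference averages are the generator's
own anchors, its values avoid branch boundaries, and quarters within a
year are identical. Real reports have boundary-straddling values,
within-year variation, missing items and vocabulary noise; tests passing
on synthetic cohorts establish the correctness of the engine's
arithmetic and contracts, not distributional realism for any province.

`recover_quality()` closes the loop: noiseless generation inverts
exactly (branch-hit agreement 100 %, totals equal truth); with moderate
noise the Spearman correlation between latent quality and scored totals
stays high (the score is a step function of quality, so saturating years
show ties); shuffling the truth is the negative control.

## Numerical and design choices

* Seeds are mandatory for the generator and threaded through the
  pipeline; RNG state is restored after every seeded operation, and
  fixed-seed pipeline runs reproduce artifacts byte for byte.
* Exact permutation p-values compare with a relative tolerance of
  10⁻¹² on the statistic to avoid float-tie artifacts.
* Zero-variance paired differences are flagged and reported as
  effect 0, p = 1, not tested.
* Free-text multi-valued fields (`E11` disinfection methods, `F01`
  equipment) are tokenized on common separators and matched
  case-insensitively against extensible vocabularies; unknown
  disinfection tokens count as one extra method with a warning note,
  unknown equipment tokens count toward the equipment total but never
  toward traceability.
* Director title and degree are ordinal vocabularies with threshold
  levels (supervising pharmacist; bachelor); unknown levels make the
  indicator undefined rather than silently failing it.

## Known limitations

* The rubric quantizes quality into at most a handful of levels per
  indicator, so rank recovery saturates at high quality.
* The cohort-derived reference fallback makes scores of a cohort depend
  on that cohort; provenance tags make this visible but it is still a
  different estimand than a configured provincial average.
* Yearly aggregation of daily-average items assumes quarters of equal
  weight.
* The sign-flip test addresses location shift between paired years; it
  is not a longitudinal model and fits no covariates.
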