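---
title: "Case-mix methods: RUG-III/HC classification, indices, and variance explained"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-mix methods: RUG-III/HC classification, indices, and variance explained}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rughc)
```

## The problem

Transitional hospital-to-home care programs deliver a relatively intense,
time-limited bundle of nursing, rehabilitation, personal support and social
services after an acute hospitalization. Planning and funding such programs
— particularly under bundled, per-episode payment — requires a case-mix
system: a classification of care episodes into groups that are clinically
meaningful and homogeneous in resource use, together with relative resource
weights per group. `rughc` implements the full analysis pipeline for the
Resource Utilization Groups version III for Home Care (RUG-III/HC) system
in this setting: classification, resource accounting with unpaid-care
valuation, case-mix indices with coefficients of variation, sample
trimming, and a variance-explained evaluation. Because client-level
assessment and billing data in this field are never public, the package
also ships a synthetic cohort generator with the statistical structure the
analysis assumes, so the entire pipeline is testable end to end.

## The classification model

The RUG-III/HC arranges clients into 7 categories evaluated in a fixed
hierarchy — Rehabilitation, Extensive services, Special care, Clinically
complex, Impaired cognition, Behaviour problems, Reduced physical
functions — and subdivides them into 23 groups by functional dependency.
Classification is a two-stage deterministic rule evaluation:

1. **Category.** Category triggers are tested in hierarchy order; the
   first satisfied trigger fixes the category. Reduced physical functions
   carries an always-true trigger, so every valid record is classified —
   totality and exclusivity hold by construction, and adding a trigger for
   a higher-ranked category can only move a client up the hierarchy.
2. **Group.** Within the category, a split map assigns the group from the
   ADL band, the IADL band and (for Extensive services) the count of
   distinct extensive services.

The ADL scale is a weighted sum of per-item dependency codes (default:
4 items coded 1–5, unit weights), banded A (score 4–7) through D (16–20);
the band is monotone in every item code. The IADL band is `"none"` exactly
when every IADL item codes below the difficulty cut-point (default: 5
items coded 0–3, cut-point 1). Within each category the lowest split is
the familiar A1/A2 distinction: band-A ADL with no IADL difficulty (x-A1)
versus band-A ADL with some IADL difficulty (x-A2).

The hierarchical skeleton and the split structure are fixed properties of
the system, but the item-level clinical triggers are instrument-specific
and are treated as **data, not code**: they ship as an editable YAML rule
configuration (`inst/extdata/rug_rules.yaml`, identical to
`default_rule_config()`). The defaults are: therapy minutes ≥ 120 per 7
days (Rehabilitation); any of IV medication, tracheostomy care, ventilator
(Extensive services); named flag lists for Special care and Clinically
complex; cognitive performance score ≥ 3 (Impaired cognition); any
behaviour flag (Behaviour problems). Users aligning the grouper with a
particular instrument revision edit the YAML, not the package. A record
missing a configured item raises a classification error rather than being
imputed — episodes with incomplete assessments are excluded, mirroring
standard practice in this literature. No tie-breaking is needed anywhere:
the hierarchy is a total order and the split map is validated to be total
(`validate_rule_config()` enumerates every reachable band combination).

## Resource accounting

Four per-episode utilization measures are computed:

- **paid hours**: the sum of billed hours over the nine provider
  disciplines (RPN, RN, OT, PT, SLP, SW, RD, PTA, PSW);
- **paid cost**: hours weighted by standardized cost weights — each
  discipline's hourly rate divided by the personal support worker (PSW)
  rate, so `weight["PSW"] == 1` exactly and cost is expressed in PSW-hour
  equivalents. Currency cancels: all downstream indices are invariant to
  rescaling every rate by a common factor;
- **combined hours / combined cost**: the paid measures plus estimated
  unpaid caregiving. Clients self-report unpaid care received in the
  preceding 3 days at admission and discharge; the episode total is the
  mean of the two reports divided by 3 (a daily rate) times the episode
  length, falling back to the admission report alone when the discharge
  report is missing. The division by 3 is deliberate: 3-day self-reports
  of roughly 10–11 hours imply ≈ 3.5 h/day and ≈ 350 h over a ≈ 99-day
  episode, the magnitudes this population exhibits; multiplying the raw
  3-day report by episode days would inflate unpaid care threefold.
  Unpaid hours are valued at replacement cost — the full PSW weight of
  1.00 per hour — acknowledging that an unpaid caregiver substitutes for
  the paid worker who would otherwise deliver equivalent care.

Episodes without billing records are excluded from the measure table (and
hence from indices and regressions) but remain classifiable and appear in
distribution tables; the exclusion count is carried as an attribute and in
the pipeline manifest.

**Trimming.** The *operational sample* removes episodes whose length falls
strictly below the 1% quantile or strictly above the 95% quantile of
episode length (defaults `low_trim = 0.01`, `high_trim = 0.05`),
approximating the intended duration of a transitional program. Quantiles
use R's type-7 (inclusive linear interpolation) convention with
strict-exceedance removal; on lengths 1..100 this removes length 1 and
lengths 96–100. The convention is exposed as an argument because published
analyses rarely state theirs, and retained-set size is non-increasing in
either trim fraction.

## Case-mix indices and coefficients of variation

For each group and measure, the case-mix index (CMI) is the group mean
divided by the overall population mean — a dimensionless relative resource
weight. Two identities hold by construction and are asserted in the tests:
the overall row's CMI is exactly 1, and the n-weighted mean of group CMIs
is 1 (to 1e-9; empty groups are excluded from numerator and denominator
consistently and reported as NA throughout). Within-group homogeneity is
summarized by the coefficient of variation, SD/mean. The sample SD (n − 1)
is the default — the quantity is an estimate from a finite sample — with a
`population` flag for the n-denominator variant; a single-member group has
SD 0 by convention, and an all-zero vector has CV 0. Groups with fewer
than 10 episodes are flagged unstable. Display output rounds CMI and CV to
two decimals; machine-readable output keeps full precision.

## Variance explained

To evaluate predictive power, each episode-level measure is regressed on
the CMI of the episode's group — four **separate** simple regressions, one
per measure, matching the one-R²-per-measure layout of this literature (a
joint four-predictor model would yield a single R²) — and the unadjusted
R² is reported. A second model adds a program indicator encoded as dummy
variables with the largest program as the (deterministic) reference level;
since the models are nested, R² cannot decrease, which the tests assert to
1e-10. When the CMI predictor is derived from the same sample being fitted,
the simple-regression R² equals the between-group share of the total sum
of squares (eta-squared), and the suite verifies this against a
brute-force decomposition. CMIs are recomputed within each sample before
fitting by default (`refit_cmi = TRUE`); reusing full-sample CMIs for the
trimmed sample is selectable, since either reading of "derive indices,
then model" is defensible. The full grid is 4 measures × 2 models × 2
samples = 16 results.

Degenerate designs fail loudly: a constant outcome, an all-constant
predictor set, or a rank-deficient design raise model errors rather than
returning a number. A sample containing a single program silently reduces
the program model to the CMI-only model, since the indicator contributes
no columns.

## What the synthetic generator emulates

`cohort_config()` defaults encode the study conditions of a transitional
hospital-to-home population:

- episode lengths from a truncated normal, mean 99.49 days, SD 35.90,
  truncated to [3, 622] — matching the printed moments and range of such
  cohorts; the truncation uses exact inverse-CDF sampling;
- a category mix of (0.104, 0.003, 0.058, 0.416, 0.020, 0.021, 0.378)
  across the 7 categories — concentrated in Clinically complex and
  Reduced physical functions — with within-category mixes dominated by
  the low-ADL groups;
- nine disciplines with PSW-dominated hours (unconditional means 13.96,
  12.84, 4.63, 5.50, 0.97, 3.59, 1.93, 9.06, 41.34 for RPN…PSW; ≈ 74 paid
  hours per episode in all), each used with a discipline-specific
  probability and lognormal conditional hours — hours are non-negative
  and right-skewed, and for unpaid care the SD exceeds the mean, which a
  normal model cannot produce;
- unpaid 3-day self-reports with mean 10.6 h and SD 17 h, drawn as a
  correlated lognormal admission/discharge pair (correlation 0.8 on the
  log scale: reports are relatively stable over an episode);
- billing records removed for 25% of episodes and discharge reports for
  10%, emulating administrative missingness;
- multiplicative group effects on expected paid and unpaid hours (default
  1.6 × 0.8^(rank−1) within each category, so expected use falls down each
  category's splits) and, optionally, program-level multipliers on paid
  hours. The program multipliers are the generator's own extension: they
  give the program-indicator model a controllable signal to detect.

The generator plants assessment items *constructively*: each episode's
target group is sampled first, then exactly the items that trigger it are
written — the target category's trigger, no higher-ranked trigger, ADL
codes composed to a score drawn inside the required band, IADL items at or
above the cut only when the split requires some difficulty. Classification
consistency (the grouper returning the planted group) is therefore
essentially exact, and the suite requires ≥ 99%.

What the generator does **not** emulate: diagnosis co-occurrence,
correlations between clinical complexity and functional dependency, care
trajectories within an episode, readmission or survival outcomes, and any
real per-program distribution. Passing tests therefore demonstrate the
pipeline's correctness and internal identities, and parameter recovery
under the stated generative model — not fidelity of any particular CMI
value to a real cohort, whose data are not publicly available.

## Problem sizes and numerical tolerances

Construction identities are asserted tightly (weighted-mean CMI to 1e-9,
eta-squared equivalence and model nesting to 1e-10). Stochastic recovery
checks use 3-standard-error bands: category shares and billing missingness
at n = 1,000–10,000 against binomial SEs, relative CMIs at n = 10,000
against delta-method SEs of the group-mean ratio (groups with n ≥ 50
only, since tiny groups carry unstable estimates, which is exactly why
the tables flag n < 10). The grouper is checked against an independent
brute-force rule-table oracle on an exhaustive grid of 2,048 synthetic
records (trigger subsets × service counts × ADL score variants × IADL
variants). These sizes keep the whole suite under a minute on one CPU
while leaving the 3-SE bands narrow enough to detect real defects.

## Known limitations

- The default clinical trigger lists are plausible placeholders for the
  instrument-specific definitions maintained elsewhere; faithful use
  against a specific grouper revision requires editing the YAML config.
- Whether the IA1 group is structurally reachable under the original
  rules cannot be settled here; the default generator mix gives it zero
  mass, matching its emptiness in observed transitional cohorts.
- The unpaid-care estimate interpolates two 3-day snapshots across the
  whole episode; volatile caregiving trajectories will be over- or
  under-counted.
- Costs are relative (PSW-hour equivalents); the package deliberately has
  no notion of currency or inflation.
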