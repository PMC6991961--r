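---
title: "Methods: time use, costing and workforce modelling for CHW programmes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time use, costing and workforce modelling for CHW programmes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chwplan)
```

`chwplan` chains four analyses a district health planner needs when
budgeting a community health worker (CHW) outreach programme: time-use
diary analytics, ingredient-based costing, a workload-based staffing model,
and stipend scenarios. This vignette documents the models, the parameters
that matter, the synthetic-data design, and the numerical conventions —
including the places where the design was genuinely open and the package
had to commit to a choice.

## The diary data model

The unit of observation is an *episode*: one timed activity by one CHW on
one diary day, with travel minutes and activity minutes recorded
separately. Diaries cover a ten-day window; home-visit episodes
additionally record visit content (what was done), conditions addressed and
up to three recipients. Activity vocabularies are district-specific because
the two service models differ (health posts in Sedibeng; Phila Mtwana
nutrition centres, war rooms and campaigns in uMzinyathi).

Validation is total: every input row is either accepted or rejected with
one categorised reason, and `rejected_rows()` exposes the audit trail. Rows
missing either duration are rejected rather than zero-imputed — medians
over silently imputed zeros would be biased low — and unknown activity
codes are rejected rather than pooled into `other`, so a mis-mapped import
surfaces as a rejection count instead of a contaminated category.

## Time-use analytics

`summarize_times()` reports episode-level medians (midpoint convention for
even counts) of travel and activity minutes per (district, activity, site
class). `share_of_time()` divides summed *combined* (travel + activity)
minutes per activity group by the cell total, because a CHW's duty time is
consumed by both walking and working; travel can exceed 40% of total time
in peri-urban Sedibeng, so shares on activity time alone would misstate the
workload mix.

`visit_composition()` needs a denominator convention, which the published
tables do not state (their columns sum to 99–118%). The package's contract,
recorded on the output as an attribute: **content** codes are counted per
home visit (a visit can involve screening *and* bringing medicines, so the
column need not sum to 1); **condition** and **recipient** codes each count
once and are normalised over all recorded codes, so those columns sum to 1.

### Inference

Durations are strongly right-skewed, so group location contrasts are median
contrasts. A 0.5-quantile regression on a binary site-class indicator has a
closed-form least-absolute-deviations solution — intercept `median(a)`,
coefficient `median(b) − median(a)` — which `median_difference_test()`
uses directly rather than running an iterative solver. The published
analysis does not state its inference method for these regressions; the
package's choice is a seeded nonparametric bootstrap (default 1,000
resamples, within-group resampling) with a two-sided percentile p-value,
`2 min(P(b* ≤ 0), P(b* ≥ 0))` with add-one smoothing, and a percentile
confidence interval. It is distribution-free, reproducible under a seed,
and its type-I error at α = 0.05 is validated in the test suite (slightly
conservative, ~0.025–0.03 under a null of identical whole-minute log-normal
groups of 100, reflecting the discreteness of sample medians on
minute-rounded data).

Episodes are treated as independent: clustering within CHW is not modelled
(the published analysis gives no indication that it was), and this is the
main caveat on the p-values for real diary data.

Overall heterogeneity across activities uses the tie-corrected
Kruskal–Wallis statistic (`stats::kruskal.test`; the test suite checks it
against a hand-written rank-formula oracle on exhaustively enumerated small
splits). Proportion contrasts use the pooled two-proportion z-test without
continuity correction, whose square is the 1-df chi-square statistic of the
2×2 table — an identity the tests verify numerically. No multiple-testing
adjustment is applied, matching the per-cell presentation convention of the
source tables. Cells are flagged significant at α = 0.05.

## The synthetic diary generator

The original diaries are not public, so the generator emulates them from
the published summary tables, and every downstream stage is exercised on
data with known truth.

* **Durations** are log-normal, `round(exp(log(m) + σZ))` floored at one
  minute, so the configured median `m` is the distribution's median by
  construction and values are whole minutes as diaries record them. Only
  medians are published; the log-scale spread σ (default 0.5, common to all
  activities) is a modelling choice and is documented as such — it is not
  recoverable from the source tables.
* **Activity mix.** Published tables give each activity's share of *time*,
  not of episodes. The generator derives episode probabilities as
  `p ∝ share / (travel_median + activity_median)`; with a common σ the
  log-normal mean is `median × exp(σ²/2)` in both components, the factor
  cancels, and the generated share of combined time matches the published
  share in expectation. Activities printed as 0% share receive small
  residual shares so each column still totals 100%.
* **Home-visit splits.** Sedibeng's 66%/57% home-visit time shares span
  three diary rows (registration, screening, other visits); the split
  across the three is unpublished and is taken as equal thirds.
* **Visit attributes.** Content codes are independent Bernoulli draws at
  the published per-visit occurrence rates. Condition codes are one
  categorical draw per visit from the published frequencies (normalised —
  the printed columns total 104–118%, so they can only be interpreted as
  relative frequencies). Recipients number 1–3 with mean 1.1 (the observed
  average), sampled without replacement from the normalised published
  frequencies.
* **Episode counts** are Poisson (mean 8/day, truncated ≥ 1); the source
  reports no episode counts, so this sets scale only. Default CHW counts
  follow the study sample: 111 CHWs in Sedibeng (68% peri-urban), 110 in
  uMzinyathi (77% deep-rural).

What passing the recovery tests shows — and does not. Medians recover
within 10% at ≥500 episodes and categorical frequencies within 3 points at
≥2,000, so the analysis stack is correct on data *of this form*. Real
diaries have features the generator deliberately omits: within-CHW
day-to-day correlation, spatial travel structure, missing and malformed
entries beyond what validation fixtures inject, and any dependence between
content, condition and recipient codes (only marginals are published).
Parameter recovery therefore validates the pipeline, not the realism of any
particular district's data.

## Costing

Every line is `unit_cost × quantity × allocation_share / life_years` —
straight-line annualization for capital items (health posts over 15 years,
training over 5, kits over 2), `life_years = 1` for recurrent items.
Allocation shares handle jointly used resources uniformly (35% of a health
post, 55% of a professional nurse's time, 50% of an assistant director)
rather than as special cases. Panel subtotals take a proportional overhead
mark-up (8% in Sedibeng, none in uMzinyathi); district per-capita and
PHC-share metrics combine all panels before dividing by population. USD
conversion uses a fixed configurable rate (default 14.3 ZAR/USD).

The reference tables carry both published unit costs and published
annualized line values. The two disagree by up to ~0.02% on a few salary
rows (the published unit costs are rounded), so reconstructions use the
published annualized values and a separate tolerance test (relative 2e-4)
ties them to the unit-cost-derived lines. Internal arithmetic is never
rounded; display rounding is half-away-from-zero to whole ZAR
(`round_half_up()`), percentages to one decimal.

`class_share()` reports expenditure shares by cost class against the
overhead-inclusive total. The package's computed management/supervision and
training shares for uMzinyathi (e.g. training 4.0%) differ from the
published narrative figures (5.8%), which do not reproduce from the
published line items under any grouping we tested; the package reports its
own arithmetic and leaves the discrepancy visible rather than matching the
narrative numbers.

## Workforce model

Required home-visit hours per 100,000 population are `Σ_s visits_s ×
minutes_s / 60` over six service types (registration, screening,
mother-and-under-5, HIV/TB, chronic, other), where `minutes_s` is the
median combined travel-plus-activity time per visit and `visits_s` comes
from an upstream demographic/burden-of-disease needs model at 70% coverage.
That upstream model is out of scope: visit counts are *inputs*, and
`derive_visit_needs()` back-derives them from per-service hours so the
packaged reconstruction is self-contained. Coverage is stored on the needs
object; alternative coverage scenarios are a single multiplicative change.

Hours available per CHW per year are `200 duty days × duty hours (6
Sedibeng / 8 uMzinyathi) × observed share of time on home visits`
(66/57/55/49% by geography). Required CHWs are `total_hours / available ×
chws_per_visit`; pair-working in Sedibeng enters as a multiplier on the
requirement (84.12 visit-slots per 100,000 staffed by two CHWs each →
168), not as a halving of available hours — the two parameterizations
differ once rounding enters, and the multiplier form reproduces the
published counts.

Rounding ladder (fixed deliberately, because the published figures mix
conventions): headline CHW counts round half-away-from-zero to integers
(168/223/137/221); the *relative* requirement between site classes uses the
**unrounded** ratio rounded to a whole percent (221.34/136.99 → 62%; the
rounded counts would give 61%); and the households-per-CHW norm scales the
250-household guideline by the unrounded ratio, `250 × (1 − (ratio − 1))`,
then rounds to whole households (169 rural, 96 deep-rural). Each convention
is part of the corresponding function's contract.

The per-service hours printed for two geographies sum to one hour more
than their printed totals (e.g. 173,531 vs 173,530) — source-table
rounding; the CHW counts are unaffected.

## Stipend scenarios

`apply_stipend()` rescales each CHW stipend line to `12 × new_stipend ×
quantity`, reapplies the overhead rate to the new subtotal, and recomputes
all metrics. Reapplying overheads to the increment is a deliberate
convention: it reproduces the published 25% Sedibeng district increase
(without it the figure is 23%). Supervisor stipends are untouched by
default; `raise_supervisors = TRUE` also lifts stipended supervisors below
the new wage (relevant only in uMzinyathi, where supervisors are
higher-level CHWs on R2,300/month — and required to reproduce the published
post-scenario per-capita figure of R48). uMzinyathi's published 71%
district increase does not reproduce from the published line items under
either convention (the package computes 68.1% CHW-only, 69.7% with
supervisors); the package reports its own computation.

## Pipeline, determinism and problem sizes

`run_pipeline()` runs every stage from one configuration and writes
machine-readable CSV reports (significance encoded as a boolean column,
never formatting), a JSON manifest with the seed and per-report digests,
and a stage-granular log with record counts, making the validation-drop
contract auditable. All randomness (generation, bootstraps) is seeded, so
reports are byte-identical under a fixed seed.

Default analysis sizes were chosen to make sampling error small relative to
the recovery tolerances while keeping any single check a desk-scale
computation: recovery tests use 60–100 synthetic CHWs (≈5,000 home-visit
episodes), bootstrap inference uses 1,000 resamples, and the type-I-error
calibration uses 200 seeded null replicates of 100-observation groups.

## Known limitations

* Episode independence: no within-CHW clustering in generation or
  inference; real-data p-values will be somewhat anti-conservative.
* The generator reproduces published marginals only; joint structure among
  visit attributes is not emulated.
* The upstream needs model behind per-service visit counts is not
  re-implemented; analyses of other districts must supply their own counts
  (or per-service hours).
* Costing covers the provider perspective only — no CHW out-of-pocket
  costs, discounting beyond straight-line depreciation, or inflation
  adjustment.
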