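# chwplan

Planning analytics for community health worker (CHW) outreach programmes.

South Africa's primary-health-care re-engineering policy deploys ward-based
outreach teams (WBOTs) of 6–10 CHWs who deliver home-based screening, health
education, medicine delivery and chronic-care support. Budgeting such a
programme requires answering three linked questions per geography type
(peri-urban, rural, deep-rural): *how do CHWs actually spend their time*,
*what does the programme cost per year*, and *how many CHWs does a
population need*? `chwplan` implements that full planning chain for
district health planners and health economists, parameterized with the
published figures from two South African districts (Sedibeng, Gauteng and
uMzinyathi, KwaZulu-Natal) and runnable end-to-end on synthetic diary data.

## What it computes

**Time-use diary analytics.** From one-row-per-episode activity diaries:
episode-level medians of travel and activity minutes per activity and site
class; share of combined (travel + activity) time per activity group; and
home-visit composition tables (content, conditions addressed, recipients
seen). Because diary durations are strongly right-skewed, group contrasts
use median (0.5-quantile) regression: for a binary site-class indicator the
least-absolute-deviations coefficient is

  b&#770;&#8321; = median(y&#7470;) − median(y&#7463;),

with a seeded within-group bootstrap for the two-sided p-value and
percentile confidence interval. Overall heterogeneity uses the
tie-corrected Kruskal–Wallis statistic, and share/composition contrasts use
the pooled two-proportion z-test (z² equals the 1-df chi-square statistic).

**Ingredient costing.** Each budget line is `unit_cost × quantity ×
allocation_share / life_years` (straight-line annualization of capital
items; recurrent items have life_years = 1), summed to panel subtotals,
marked up by district overheads, and expressed as district total, cost per
capita, cost per CHW and percent of PHC expenditure per capita.

**Workforce requirements.** A workload model in the WISN spirit: required
home-visit hours per 100,000 population are `Σ_s visits_s ×
minutes_s / 60` over service types; hours available per CHW per year are
`duty_days × duty_hours × share_of_time_on_home_visits`; required CHWs are
`total_hours / available_hours × chws_per_visit` (CHWs work in pairs in
Sedibeng). The unrounded requirement ratio between site classes scales the
250-households-per-CHW guideline norm down for rural and deep-rural areas.

**Stipend scenarios.** Raising the CHW stipend to the national minimum wage
(R3,500/month) rescales the stipend lines, reapplies overheads and
recomputes every cost metric.

## Worked example

How many CHWs does a fully deep-rural district of 100,000 people need?

```r
library(chwplan)
wf <- ref_workforce_requirements()
wf$by_site$umzinyathi_deep_rural
#> CHW workforce requirement (per 100,000 population)
#>   home-visit hours required: 173,531
#>   hours available per CHW:   784
#>   CHWs per visit:            1
#>   CHWs required:             221 (unrounded 221.34)
```

221 CHWs — 62% more than the 137 a fully peri-urban district would need
(`wf$relative`), which is why the households-per-CHW norm falls from 250
(peri-urban) to 96 (deep-rural) in `wf$households`.

What does the uMzinyathi programme cost per year?

```r
summarize_costs(ref_cost_model("umzinyathi"), "district")
#> Cost summary: umzinyathi / district (481 CHWs)
#>   ...
#>   Total                                     14,404,985
#>   per CHW: R29,948
```

R14.4 million a year, R29,948 per CHW — 2.4% of the district's PHC
expenditure per capita. And the minimum-wage scenario for Sedibeng:

```r
apply_stipend(ref_cost_model("sedibeng"),
              stipend_scenario("sedibeng", 2500, 3500))
#> Stipend scenario: sedibeng, R2,500 -> R3,500 per month
#>   stipend increase:        40%
#>   district expenditure:    R44,089,191 -> R55,079,271 (+24.9%)
#>   per capita:              R47 -> R59
#>   share of PHC spend:      3.9% -> 4.9%
```

A 40% stipend rise lifts district expenditure by 25% but keeps the
programme under 5% of PHC spending.

The diary side runs the same way on synthetic data:

```r
d <- generate_diaries(default_config("umzinyathi", "deep_rural",
                                     n_chws = 100, seed = 1))
subset(summarize_times(d), activity_code == "home_visit")
#>     district activity_code site_class median_travel median_activity n_episodes
#> 4 umzinyathi    home_visit deep_rural            20              60       5188
```

recovering the configured 20/60-minute medians; `run_pipeline(run_config(
"out"))` writes every report table (medians, shares, composition,
significance tests, costs, utilization, workforce, households, scenario)
plus a manifest and log.

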