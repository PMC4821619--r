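# robmeta

Risk-of-bias stratified meta-analysis of non-randomized studies.

Systematic reviews of drug safety increasingly pool non-randomized
studies, whose large inverse-variance weights can let biased estimates
dominate the synthesis. `robmeta` implements the full re-analysis
pipeline for grading and stress-testing such reviews:

- **Domain-based risk-of-bias (RoB) assessment** — seven ordinal domain
  judgments per study (`low < moderate < serious < critical`) aggregated
  into an overall rating by the worst-domain rule, with a configurable
  escalation policy for multiple moderate/serious domains
  (`aggregate_overall()`, `classify_studies()`, `count_by_level()`).
- **Generic inverse-variance pooling on the log scale** — fixed-effect
  and DerSimonian–Laird random-effects models. For study *i* with log
  effect *yᵢ* and standard error *seᵢ* (back-calculated from the
  published CI as *se = (ln U − ln L)/(2·1.959964)*):
  *w*ᵢ = 1/*se*ᵢ², Q = Σ*w*ᵢ(*y*ᵢ − ȳ*w*)²,
  τ̂² = max(0, (Q − (k−1)) / (Σ*w*ᵢ − Σ*w*ᵢ²/Σ*w*ᵢ)),
  random-effects weights 1/(*se*ᵢ² + τ̂²), z-based CIs, and
  I² = 100·max(0, (Q − df)/Q) always from the fixed-effect Q
  (`to_log_effect()`, `random_effects_pool()`, `pool_by_subgroup()`).
- **RoB-stratified sensitivity analysis** — re-pool after excluding
  studies above a maximum acceptable overall RoB (Analysis A: drop
  serious/critical; Analysis B: additionally drop moderate) and report
  excluded studies, estimate shifts, significance changes and
  heterogeneity traces (`filter_by_rob()`, `run_sensitivity()`,
  `heterogeneity_trace()`).
- **Two-rater agreement** — Cohen's kappa with linear weights
  *w*ᵢⱼ = 1 − |i−j|/(k−1) over a declared ordered category set
  (`weighted_kappa()`).
- **Seeded synthetic-data generators** with known truth for validating
  every stage (`simulate_effect_set()`, `simulate_rob_profiles()`,
  `simulate_rating_pairs()`).

The study-level inputs of two published cardiovascular-safety reviews —
16 thiazolidinedione studies (31 estimates) and 21 COX-2
inhibitor/NSAID studies (66 estimates), with their consensus domain
judgments — ship as plain-CSV fixtures (`load_fixture()`).

## Worked example

Classify the thiazolidinedione studies, pool myocardial infarction, and
re-pool keeping only low-RoB studies:

```r
library(robmeta)

tzd <- load_fixture("tzd_effects")
cls <- classify_studies(load_fixture("tzd_rob"))
count_by_level(cls)
#>      low moderate  serious critical
#>        6        4        4        2

mi <- tzd[tzd$outcome == "myocardial_infarction", ]
pool_by_subgroup(mi)$overall
#> Random-effects inverse-variance pool, k = 15
#>   1.16 (95% CI 1.07-1.24)
#>   Q = 25.81 (df = 14), tau2 = 0.0079, I2 = 46%

run_sensitivity(mi, cls, rob_scenario("analysis_B"))
#> <sensitivity_report: tzd_effects> scenario analysis_B (retain <= low)
#>   original: k = 15, overall 1.16 (1.07-1.24)
#>   post:     k = 6, overall 1.06 (0.99-1.13)
#>   delta_log = -0.0868, significance lost
#>   excluded: bilik_2010 (serious), brownstein_2010 (serious), hsiao_2009 (critical), koro_2008 (serious), lipscombe_2007 (moderate), margolis_2008 (serious), stockl_2009 (moderate), tzoulaki_2009 (moderate), ziyadeh_2009 (moderate)
```

Read: across all 15 studies, rosiglitazone carries a significantly
elevated pooled myocardial-infarction risk relative to pioglitazone
(RR 1.16, 95% CI 1.07–1.24, I² = 46%). Restricting to the six studies
judged at low risk of bias moves the estimate to 1.06 (0.99–1.13) — no
longer statistically significant: the apparent excess risk rests on the
higher-RoB studies.

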