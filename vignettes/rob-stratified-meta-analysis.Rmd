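---
title: "Risk-of-bias stratified meta-analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-of-bias stratified meta-analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robmeta)
```

## The problem

Meta-analyses of non-randomized studies inherit whatever systematic error
their component studies carry. Because large administrative-database
studies receive large inverse-variance weights, a single confounded study
can dominate a pooled relative risk. The defensible response is not to
discard non-randomized evidence but to *grade* it — judge each study's
risk of bias (RoB) domain by domain, derive an overall rating, and ask
whether the pooled estimate survives when only the lower-RoB studies are
retained. robmeta implements that pipeline end to end and ships, as
plain-CSV fixtures, the study-level inputs of two published safety
reviews (thiazolidinediones and myocardial infarction / heart failure /
mortality; individual NSAIDs and cardiovascular events) on which the
pipeline can be exercised against known published outputs.

## Domain-based RoB assessment

Each study receives one ordinal judgment per bias domain on the scale
low < moderate < serious < critical. The seven domains follow the
chronology of a non-randomized study: confounding and participant
selection (pre-intervention), measurement of the intervention (at
intervention), then departures from intended intervention, missing data,
outcome measurement, and selective reporting (post-intervention).

The overall rating is, at base, the worst domain judgment: *low* only if
every domain is low; *moderate* if all are low/moderate with at least one
moderate; *serious* if any domain is serious and none critical;
*critical* if any domain is critical. On top of this the instrument
grants reviewers discretion to treat multiple moderate (or serious)
judgments as additive — several moderates may justify an overall
*serious*, several seriouses an overall *critical*.

`aggregate_overall()` makes that discretion explicit as an
`escalation_policy()` with two count thresholds. The default threshold is
**3 domains** for both steps. The design space here was genuinely open —
the instrument says only "multiple domains" — and we fixed the threshold
empirically: 3 is the unique integer rule that reproduces all 37
published consensus overall ratings in the packaged fixtures. Studies
with two moderate domains stayed moderate in the consensus; studies with
three or four moderate domains were rated serious; the one study with
three serious domains was rated critical. Escalation is applied once per
aggregation (no moderate → serious → critical cascade): no published
consensus exhibits a cascade, and the single-step rule is the simplest
one consistent with the data. Both thresholds are configurable, and
`classify_studies()` records concordance whenever a consensus column is
available, so the rule's adequacy on new data is itself measurable.

```{r}
cls <- classify_studies(load_fixture("cox2_rob"))
count_by_level(cls)
sum(cls$concordant)
```

## The pooling model

Study effects enter on the natural-log scale. For a study reporting a
ratio estimate $r$ with a $(1-\alpha)$ CI $(L, U)$,

$$y = \ln r, \qquad
  \widehat{se}(y) = \frac{\ln U - \ln L}{2 z_{1-\alpha/2}},$$

with $z_{0.975} = 1.959964$. This back-calculation is exact for Wald-type
intervals, which is how the source studies' regression models report.
The five ratio measures (OR, HR, RR, IRR, ReR) are pooled
interchangeably on the log scale, as the source reviews did; the measure
label is retained for reporting only. Rare-outcome ratios are close
enough that mixing them changes nothing material, and the published
pooled rows mix them without distinction.

The fixed-effect pool uses weights $w_i = 1/se_i^2$; Cochran's
$Q = \sum_i w_i (y_i - \bar y_w)^2$. The between-study variance uses the
DerSimonian–Laird moment estimator

$$\hat\tau^2 = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

and the random-effects pool re-weights by $w_i^* = 1/(se_i^2 +
\hat\tau^2)$ with a z-based CI on the pooled log effect. Three
conventions are fixed deliberately, matching the mainstream
review-software behaviour the published tables were produced with:

* **DL, not REML or Paule–Mandel** — the moment estimator is what the
  published pooled rows used; offering alternatives would invite silent
  mismatches in replication work.
* **z-based CIs, not Hartung–Knapp** — same reason.
* **$I^2 = 100\max(0, (Q - df)/Q)$ always computed from the fixed-effect
  $Q$**, regardless of the pooling model — the standard definition.

With one study, $Q$ is defined as exactly 0 (the floating-point
round-trip $\sum w y / \sum w$ can otherwise leave a spurious residual
that turns $0/0$ into $I^2 = 100$), and the pool reduces to the study
itself. $\hat\tau^2$ with $k = 1$ returns 0 with a warning rather than
an error, so that degenerate strata still report.

Stratified syntheses (`pool_by_subgroup()`) estimate a separate
$\hat\tau^2$ inside each design stratum (cohort / case-control) *and*
one more on the union of all studies for the overall column. The overall
is a single synthesis, not a combination of stratum summaries — this is
what reproduces the published overall CIs, which are narrower than
either stratum's.

robmeta authors these formulas directly rather than delegating to a
meta-analysis package, because the exact conventions above *are* the
substance being validated; the test suite cross-checks every fixture
pool against `metafor::rma(method = "DL")` to 1e-10 as an independent
reference.

## Sensitivity analysis by RoB stratum

`rob_scenario("analysis_A")` retains studies up to moderate overall RoB;
`"analysis_B"` retains only low. `run_sensitivity()` pools before and
after filtering and reports the excluded studies, the shift in the
pooled log effect, and whether statistical significance — defined solely
as the 95% CI excluding 1, the convention of the source reviews — was
gained, lost, or unchanged. "No change" is flagged when the pre- and
post-estimates agree at the 2-decimal reporting precision (estimate and
both CI bounds), mirroring how published comparison tables mark
unchanged cells; full-precision deltas remain in the report object.

```{r}
tzd <- load_fixture("tzd_effects")
cls_tzd <- classify_studies(load_fixture("tzd_rob"))
mi <- tzd[tzd$outcome == "myocardial_infarction", ]
run_sensitivity(mi, cls_tzd, rob_scenario("analysis_B"))
```

## What the fixtures contain, exactly

The fixtures transcribe the published study tables verbatim, at their
printed two-decimal precision, with no re-derivation from participant
counts. Points where the printed record is internally inconsistent are
preserved, not repaired:

* One diclofenac interval (1.68, CI 1.14–4.29) is implausibly asymmetric
  around its estimate — a suspected typo in the source. It is stored
  verbatim; validation tolerates one unit in the last printed decimal
  when checking that an estimate lies inside its own CI.
* One case–control study of the NSAID review prints a RoB profile but no
  per-drug effect estimates; it appears in the RoB fixture (21 profiles)
  and not in the effects fixture (20 studies, 66 estimates).
* One study is labelled case–control in the study-description table but
  cohort in the RoB table; the fixture stores cohort, which is the only
  assignment that reproduces the published cohort-stratum pooled rows.
* The thiazolidinedione table prints 9 heart-failure and 7 mortality
  estimates, while the published pooled rows claim n = 8 for both. The
  fixtures store what is printed. Pooling all 9 printed heart-failure
  rows reproduces one of the two (mutually inconsistent) published
  "original" heart-failure rows to ±0.01; the other, and the published
  heart-failure heterogeneity trace (41% → 41% → 16%), cannot be
  reproduced from any subset of the printed inputs — the printed
  case–control heart-failure cell could not have come from the single
  printed case–control heart-failure study. The acceptance test for that
  one trace value is expected to fail, and is kept failing rather than
  loosened, as an honest record of the discrepancy. Likewise the
  published all-study ibuprofen lower CI bound (0.97) computes to 0.95
  from the printed inputs, just outside the ±0.01 comparison band,
  while the estimate and upper bound reproduce.

## The synthetic-data generators

`simulate_effect_set()` draws, per study, an overall RoB level, a true
log effect $\theta_i \sim N(\mu + b_{\mathrm{level}}, \tau^2)$, a
sampling SE uniform on a configurable range, and an observed
$y_i \sim N(\theta_i, se_i^2)$, emitting a fully valid effect set plus a
truth record. Defaults are fixed once to describe a realistic review of
this kind: the SE range (0.05–0.35) spans the SEs back-calculated from
the fixtures; the RoB level mix (8 low / 18 moderate / 9 serious /
2 critical out of 37) and the cohort share (17/37) are the empirical mix
of the fixture studies. The bias mechanism — an additive log-scale shift
attached to higher-RoB levels, zero by default — is the simplest
structure under which "excluding high-RoB studies moves the pool toward
the truth" is a testable claim, and the test suite verifies exactly that
over 200 replicates.

What the generator does *not* emulate: correlated effects from shared
populations, non-normal sampling error in sparse-event studies,
selective publication, or any association between a study's SE and its
RoB (in real reviews the larger studies are often the better-rated
ones). Passing the simulation tests therefore shows the estimators are
correct under the model's own assumptions, not that the model captures
every feature of real review data.

All generators take an explicit seed, reproduce bit-identically under
it, and restore the caller's RNG stream, so no package function ever
consumes ambient randomness.

## Numerical and validation details

* Validation of transcribed estimates tolerates one unit in the last
  printed decimal when checking CI ordering; everything else
  (positivity, `ci_level` in (0,1), uniqueness of study × outcome ×
  exposure) is strict, and errors name the offending rows.
* Weighted kappa (`weighted_kappa()`) uses linear agreement weights
  $w_{ij} = 1 - |i-j|/(k-1)$ over the *full declared* category set —
  unobserved categories keep their zero margins, which changes expected
  agreement and is therefore an explicit, documented choice (the
  alternative, collapsing to observed categories, is available by
  passing a smaller category set). Two raters constant on the same
  single category make expected agreement 1 and kappa undefined; this
  errors, distinct from kappa = 1. No CI is attached by default; an
  optional seeded bootstrap over units is provided. The published
  per-domain kappa values themselves are not reproducible — the two
  raters' pre-consensus judgments were never published — so the
  statistic is validated against a brute-force oracle and on synthetic
  raters instead.
* Simulation scale in the test suite: parameter recovery runs 500
  replicates of k = 200 studies (bias of the pooled log effect within 3
  Monte-Carlo SEs; DL $\hat\tau^2$ relative bias ≤ 15% at
  $\tau^2 = 0.05$; 95% CI coverage within 93–97% at $\tau^2 = 0$),
  sizes at which the whole suite completes in well under a minute.

## Limitations

The escalation threshold of 3 is a sufficient formalization of the
published consensus behaviour, not necessarily the reviewers' intended
rule; on other datasets the policy should be re-examined against any
available consensus ratings (the concordance report makes this cheap).
The package pools only ratio measures via log-normal approximation — no
mean differences, no exact small-count methods, no meta-regression,
funnel plots, or leave-one-out diagnostics. RoB judgments are taken as
given per study; per-outcome domain variation is not modelled (the
source assessments did not differ by outcome).
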