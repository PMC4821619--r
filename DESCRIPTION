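Package: robmeta
Title: Risk-of-Bias Stratified Meta-Analysis of Non-Randomized Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for re-analysing meta-analyses of non-randomized studies
    under domain-based risk-of-bias (RoB) assessment. Implements the
    ACROBAT-NRSI/ROBINS-I style aggregation of seven ordinal domain
    judgments into an overall study rating (including the multi-domain
    escalation discretion), generic inverse-variance fixed-effect and
    DerSimonian-Laird random-effects pooling of relative risks on the log
    scale with Cochran's Q, tau-squared and I-squared heterogeneity
    statistics, RoB-stratified sensitivity re-analysis with before/after
    comparison reports, and two-rater agreement via linearly weighted
    Cohen's kappa. Ships the study-level effect estimates and consensus
    domain judgments of two published pharmacoepidemiological reviews
    (thiazolidinediones and COX-2 inhibitors versus adverse cardiovascular
    events) as packaged fixtures, plus seeded generators of synthetic
    effect sets, domain profiles and paired ratings for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
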