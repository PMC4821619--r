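# Minimal valid effect-set rows for constructing test inputs.
make_effects <- function(estimate, ci_low, ci_high,
                         study_id = sprintf("s%02d", seq_along(estimate)),
                         design = "cohort", outcome = "o", exposure = "x",
                         measure = "RR", ...) {
  effect_set(data.frame(study_id = study_id, design = design,
                        measure = measure, outcome = outcome,
                        exposure = exposure, estimate = estimate,
                        ci_low = ci_low, ci_high = ci_high, ...,
                        stringsAsFactors = FALSE))
}

# Log-effect data frame straight from y/se, bypassing the CI encoding.
make_log_effects <- function(y, se, study_id = sprintf("s%02d", seq_along(y)),
                             design = "cohort") {
  data.frame(study_id = study_id, design = rep_len(design, length(y)),
             y = y, se = se, stringsAsFactors = FALSE)
}

# A complete domain profile, defaulting every domain to "low".
make_profile <- function(...) {
  p <- setNames(rep("low", 7), rob_domains())
  over <- list(...)
  p[names(over)] <- unlist(over)
  p
}
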