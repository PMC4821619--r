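#' Sensitivity-analysis scenarios
#'
#' A scenario names the maximum overall RoB level a study may carry and
#' still be pooled. Two standard scenarios mirror the published
#' re-analyses: *Analysis A* excludes studies with serious or critical
#' overall RoB (retains up to `moderate`), *Analysis B* additionally
#' excludes moderate ones (retains only `low`).
#'
#' @param name `"analysis_A"`, `"analysis_B"`, or `"custom"`.
#' @param max_level Highest retained level; fixed at `"moderate"` for
#'   `analysis_A` and `"low"` for `analysis_B`, required for `"custom"`.
#' @return A list of class `"rob_scenario"` with `name` and `max_level`.
#' @export
rob_scenario <- function(name = c("analysis_A", "analysis_B", "custom"),
                         max_level = NULL) {
  name <- match.arg(name)
  implied <- switch(name, analysis_A = "moderate", analysis_B = "low",
                    custom = NULL)
  if (is.null(implied)) {
    if (is.null(max_level))
      .stopf("a custom scenario needs an explicit `max_level`")
  } else {
    if (!is.null(max_level) && !identical(max_level, implied))
      .stopf("%s is defined by max_level = \"%s\"", name, implied)
    max_level <- implied
  }
  .rob_rank(max_level, "max_level")
  structure(list(name = name, max_level = max_level),
            class = "rob_scenario")
}

#' Filter an effect set by maximum acceptable overall RoB
#'
#' Retains exactly the effects whose study is classified at or below
#' `max_level`, preserving row order. Every study in `set` must appear in
#' the classification; filtering at `max_level = "critical"` is the
#' identity.
#'
#' @param set An [effect_set()].
#' @param classification A [classify_studies()] result, a named character
#'   vector `study_id -> level`, or a data frame with `study_id` and
#'   `overall` (e.g. a fixture's consensus column via
#'   `load_fixture("tzd_rob")[, c("study_id", "overall")]`).
#' @param max_level Highest retained level, one of [rob_levels()].
#' @return The filtered [effect_set()].
#' @examples
#' tzd <- load_fixture("tzd_effects")
#' mi <- tzd[tzd$outcome == "myocardial_infarction", ]
#' cls <- classify_studies(load_fixture("tzd_rob"))
#' nrow(filter_by_rob(mi, cls, "moderate"))  # 10 of 15 studies retained
#' @export
filter_by_rob <- function(set, classification, max_level) {
  stopifnot(inherits(set, "effect_set"))
  lv <- .classification_levels(classification)
  unclassified <- setdiff(unique(set$study_id), names(lv))
  if (length(unclassified))
    .stopf("study without a RoB classification: %s",
           paste(unclassified, collapse = ", "))
  keep <- .rob_rank(lv[set$study_id], "overall judgment") <=
    .rob_rank(max_level, "max_level")
  set[keep, , drop = FALSE]
}

#' RoB-stratified sensitivity re-analysis
#'
#' Pools the full set and the RoB-filtered set via [pool_by_subgroup()]
#' and reports the comparison: excluded studies, the shift in the pooled
#' log effect, whether statistical significance (95% CI excluding 1) was
#' gained, lost or unchanged, and -- stratum by stratum -- whether the
#' re-analysis changed anything at the 2-decimal reporting precision
#' ("no change" cells).
#'
#' @param set An [effect_set()] for a single outcome/exposure.
#' @param classification See [filter_by_rob()].
#' @param scenario A [rob_scenario()].
#' @param model,ci_level Passed to [pool_by_subgroup()].
#' @return A `"sensitivity_report"`: list with `label`, `scenario`,
#'   `original` and `post` (`"subgroup_result"`s; `post` is `NULL` and
#'   flagged not estimable when no study survives), `excluded`
#'   (data frame `study_id`, `overall`), `n_original`, `n_post`,
#'   `delta_log`, `significance_change`, and `no_change` (named logical
#'   per stratum and overall).
#' @examples
#' cox2 <- load_fixture("cox2_effects")
#' ibu <- cox2[cox2$exposure == "ibuprofen", ]
#' cls <- classify_studies(load_fixture("cox2_rob"))
#' run_sensitivity(ibu, cls, rob_scenario("analysis_A"))
#' @export
run_sensitivity <- function(set, classification, scenario = rob_scenario("analysis_A"),
                            model = "random", ci_level = 0.95) {
  stopifnot(inherits(set, "effect_set"), inherits(scenario, "rob_scenario"))
  lv <- .classification_levels(classification)
  post_set <- filter_by_rob(set, classification, scenario$max_level)
  dropped <- setdiff(unique(set$study_id), unique(post_set$study_id))
  excluded <- data.frame(study_id = dropped,
                         overall = unname(lv[dropped]),
                         stringsAsFactors = FALSE)

  original <- pool_by_subgroup(set, model = model, ci_level = ci_level)
  post <- if (nrow(post_set)) pool_by_subgroup(post_set, model = model,
                                               ci_level = ci_level) else NULL

  sig <- function(p) p$ci_low > 1 || p$ci_high < 1
  significance_change <- if (is.null(post)) NA_character_ else {
    before <- sig(original$overall); after <- sig(post$overall)
    if (before == after) "unchanged" else if (after) "gained" else "lost"
  }

  same_printed <- function(a, b) {
    !is.null(a) && !is.null(b) &&
      all(round(c(a$estimate, a$ci_low, a$ci_high), 2) ==
            round(c(b$estimate, b$ci_low, b$ci_high), 2))
  }
  strata <- union(names(original$per_group),
                  if (!is.null(post)) names(post$per_group) else character())
  no_change <- c(
    setNames(vapply(strata, function(g)
      same_printed(original$per_group[[g]], post$per_group[[g]]), logical(1)),
      strata),
    overall = same_printed(original$overall, post$overall))

  structure(list(
    label = attr(set, "label"),
    scenario = scenario,
    original = original,
    post = post,
    excluded = excluded,
    n_original = length(unique(set$study_id)),
    n_post = length(unique(post_set$study_id)),
    delta_log = if (is.null(post)) NA_real_ else
      post$overall$pooled_log - original$overall$pooled_log,
    significance_change = significance_change,
    no_change = no_change), class = "sensitivity_report")
}

#' Heterogeneity across sensitivity scenarios
#'
#' For each outcome in `set` and each scenario, pools the overall
#' synthesis and records its I-squared: how much between-study
#' heterogeneity survives as higher-RoB studies are excluded.
#'
#' @param set An [effect_set()], possibly spanning several outcomes.
#' @param classification See [filter_by_rob()].
#' @param scenarios A named list of [rob_scenario()]s, or a character
#'   vector using the shorthand `"none"` (retain everything),
#'   `"analysis_A"`, `"analysis_B"`. Defaults to all three.
#' @param model Pooling model.
#' @return A data frame with `outcome`, `scenario`, `k` (studies pooled;
#'   0 when none survive) and `i2` (`NA` when not estimable).
#' @examples
#' tzd <- load_fixture("tzd_effects")
#' cls <- classify_studies(load_fixture("tzd_rob"))
#' heterogeneity_trace(tzd, cls)
#' @export
heterogeneity_trace <- function(set, classification,
                                scenarios = c("none", "analysis_A", "analysis_B"),
                                model = "random") {
  stopifnot(inherits(set, "effect_set"))
  if (is.character(scenarios)) {
    scenarios <- setNames(lapply(scenarios, function(s)
      if (s == "none") rob_scenario("custom", "critical") else rob_scenario(s)),
      scenarios)
  }
  rows <- list()
  for (outc in unique(set$outcome)) {
    sub <- set[set$outcome == outc, , drop = FALSE]
    for (nm in names(scenarios)) {
      kept <- filter_by_rob(sub, classification, scenarios[[nm]]$max_level)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = outc, scenario = nm,
        k = length(unique(kept$study_id)),
        i2 = if (nrow(kept)) pool_by_subgroup(kept, model)$overall$i2 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  fmt <- function(p) sprintf("%.2f (%.2f-%.2f)", p$estimate, p$ci_low, p$ci_high)
  cat(sprintf("<sensitivity_report%s> scenario %s (retain <= %s)\n",
              if (is.null(x$label)) "" else paste0(": ", x$label),
              x$scenario$name, x$scenario$max_level))
  cat(sprintf("  original: k = %d, overall %s\n",
              x$n_original, fmt(x$original$overall)))
  if (is.null(x$post)) {
    cat("  post:     not estimable (no study retained)\n")
  } else {
    cat(sprintf("  post:     k = %d, overall %s%s\n", x$n_post,
                fmt(x$post$overall),
                if (isTRUE(x$no_change[["overall"]])) "  [no change]" else ""))
    cat(sprintf("  delta_log = %+.4f, significance %s\n",
                x$delta_log, x$significance_change))
  }
  if (nrow(x$excluded))
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%s (%s)", x$excluded$study_id,
                              x$excluded$overall), collapse = ", ")))
  invisible(x)
}
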