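#' The ordinal risk-of-bias scale and the seven bias domains
#'
#' Risk of bias is judged on a four-level ordered scale,
#' `low < moderate < serious < critical`, both per domain and overall.
#' The seven domains follow the chronology of a non-randomized study:
#' pre-intervention (`confounding`, `selection`), at intervention
#' (`measurement_intervention`), and post-intervention (`departures`,
#' `missing_data`, `measurement_outcome`, `reported_result`).
#'
#' @return `rob_levels()` returns the four level names in increasing
#'   severity; `rob_domains()` the seven domain keys in chronological
#'   order.
#' @export
rob_levels <- function() c("low", "moderate", "serious", "critical")

#' @rdname rob_levels
#' @export
rob_domains <- function() c("confounding", "selection",
                            "measurement_intervention", "departures",
                            "missing_data", "measurement_outcome",
                            "reported_result")

# Integer rank of a level vector (low = 1 ... critical = 4), with
# validation.
.rob_rank <- function(x, what = "judgment") {
  r <- match(x, rob_levels())
  if (anyNA(r))
    .stopf("invalid RoB %s: %s", what,
           paste(unique(x[is.na(r)]), collapse = ", "))
  r
}

#' Escalation policy for the overall RoB judgment
#'
#' The domain-to-overall aggregation gives reviewers discretion to treat
#' several moderate (or serious) domain judgments as additive: moderate
#' risks in multiple domains may raise the overall judgment to serious,
#' and serious risks in multiple domains to critical. The policy makes
#' that discretion explicit and reproducible as two count thresholds.
#' The default threshold of 3 for both steps is the smallest rule that
#' reproduces every published consensus overall in the packaged fixtures
#' (studies with two moderate domains stay moderate; studies with three
#' or four become serious).
#'
#' @param moderate_to_serious Number of domains at exactly `moderate`
#'   (>= 2) at which a would-be moderate overall escalates to serious.
#' @param serious_to_critical Number of domains at exactly `serious`
#'   (>= 2) at which a would-be serious overall escalates to critical.
#' @param enabled Set `FALSE` to disable escalation entirely, leaving the
#'   base (maximum-domain) rule.
#' @return A list of class `"escalation_policy"`.
#' @export
escalation_policy <- function(moderate_to_serious = 3L,
                              serious_to_critical = 3L,
                              enabled = TRUE) {
  for (thr in c(moderate_to_serious, serious_to_critical))
    if (!is.numeric(thr) || length(thr) != 1L || thr < 2)
      .stopf("escalation thresholds must be single counts >= 2 (a single domain never escalates)")
  structure(list(moderate_to_serious = as.integer(moderate_to_serious),
                 serious_to_critical = as.integer(serious_to_critical),
                 enabled = isTRUE(enabled)),
            class = "escalation_policy")
}

#' Aggregate seven domain judgments into an overall RoB rating
#'
#' Base rule: the overall judgment is the worst domain judgment -- low
#' only when *all* domains are low, moderate when all are low or moderate
#' with at least one moderate, serious when at least one domain is serious
#' and none critical, critical when any domain is critical. On top of the
#' base rule an [escalation_policy()] may raise a moderate overall to
#' serious (when enough domains sit at exactly moderate) or a serious
#' overall to critical (enough domains at exactly serious). Escalation is
#' applied once; it never cascades moderate -> serious -> critical within
#' a single aggregation.
#'
#' @param domains A named character vector (or single-row data frame /
#'   list) holding one judgment per domain key of [rob_domains()].
#' @param policy An [escalation_policy()].
#' @return One of `rob_levels()`.
#' @examples
#' aggregate_overall(c(confounding = "moderate", selection = "low",
#'   measurement_intervention = "moderate", departures = "moderate",
#'   missing_data = "low", measurement_outcome = "low",
#'   reported_result = "low"))  # three moderates escalate to "serious"
#' @export
aggregate_overall <- function(domains, policy = escalation_policy()) {
  stopifnot(inherits(policy, "escalation_policy"))
  if (is.data.frame(domains)) {
    if (nrow(domains) != 1L)
      .stopf("`domains` must describe a single study; got %d rows", nrow(domains))
    domains <- unlist(domains[, intersect(names(domains), rob_domains())])
  }
  domains <- unlist(domains)
  missing_dom <- setdiff(rob_domains(), names(domains))
  if (length(missing_dom))
    .stopf("incomplete profile: missing domain(s) %s",
           paste(missing_dom, collapse = ", "))
  r <- .rob_rank(domains[rob_domains()])

  base <- max(r)  # all-low => 1; >=1 moderate & none worse => 2; etc.
  out <- base
  if (policy$enabled) {
    if (base == 2L && sum(r == 2L) >= policy$moderate_to_serious) out <- 3L
    if (base == 3L && sum(r == 3L) >= policy$serious_to_critical) out <- 4L
  }
  rob_levels()[out]
}

#' Read or write a RoB judgment CSV
#'
#' Schema:
#' `study_id,confounding,selection,measurement_intervention,departures,missing_data,measurement_outcome,reported_result[,overall]`,
#' one row per study, each cell one of [rob_levels()]. The optional
#' `overall` column carries a consensus overall judgment (as in the
#' packaged fixtures); when absent it can be derived with
#' [classify_studies()].
#'
#' @param path Path to a CSV file.
#' @return `read_rob_csv()` returns a data frame of class `"rob_table"`;
#'   `write_rob_csv()` invisibly returns `path`.
#' @export
read_rob_csv <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  rob_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @param tab A `"rob_table"`.
#' @rdname read_rob_csv
#' @export
write_rob_csv <- function(tab, path) {
  stopifnot(inherits(tab, "rob_table"))
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param x A data frame with `study_id`, the seven domain columns and
#'   optionally `overall`.
#' @rdname read_rob_csv
#' @export
rob_table <- function(x) {
  need <- c("study_id", rob_domains())
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    .stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in setdiff(names(x), "study_id")) .rob_rank(x[[col]], col)
  if (anyDuplicated(x$study_id))
    .stopf("duplicate study_id: %s",
           paste(unique(x$study_id[duplicated(x$study_id)]), collapse = ", "))
  keep <- c(need, intersect("overall", names(x)))
  rownames(x) <- NULL
  structure(x[, keep], class = c("rob_table", "data.frame"))
}

#' Derive overall RoB ratings for a table of studies
#'
#' Applies [aggregate_overall()] to every profile. When the table carries
#' a consensus `overall` column, the derived ratings are compared against
#' it and the agreement is recorded in the result.
#'
#' @param tab A `"rob_table"` (see [read_rob_csv()]).
#' @param policy An [escalation_policy()].
#' @return A data frame of class `"rob_classification"` with columns
#'   `study_id`, `overall` (derived), and -- when a consensus column was
#'   present -- `consensus` and logical `concordant`.
#' @examples
#' cls <- classify_studies(load_fixture("cox2_rob"))
#' count_by_level(cls)
#' @export
classify_studies <- function(tab, policy = escalation_policy()) {
  stopifnot(inherits(tab, "rob_table"))
  derived <- vapply(seq_len(nrow(tab)), function(i)
    aggregate_overall(tab[i, rob_domains()], policy), character(1))
  out <- data.frame(study_id = tab$study_id, overall = derived,
                    stringsAsFactors = FALSE)
  if (!is.null(tab$overall)) {
    out$consensus <- tab$overall
    out$concordant <- out$overall == out$consensus
  }
  structure(out, class = c("rob_classification", "data.frame"))
}

#' Count studies per overall RoB level
#'
#' @param classification A `"rob_classification"` from
#'   [classify_studies()], a named character vector
#'   (study_id -> level), or any data frame with `study_id` and `overall`.
#' @return A named integer vector over `rob_levels()` summing to the
#'   number of studies.
#' @export
count_by_level <- function(classification) {
  lv <- .classification_levels(classification)
  out <- table(factor(lv, levels = rob_levels()))
  setNames(as.integer(out), rob_levels())
}

# Accept a classification in any supported shape and return a named
# character vector study_id -> level.
.classification_levels <- function(classification) {
  if (is.data.frame(classification)) {
    if (!all(c("study_id", "overall") %in% names(classification)))
      .stopf("classification data frame needs `study_id` and `overall` columns")
    lv <- setNames(classification$overall, classification$study_id)
  } else if (is.character(classification)) {
    lv <- classification
  } else .stopf("unsupported classification object")
  if (length(lv)) .rob_rank(lv, "overall judgment")
  lv
}

#' @export
print.rob_table <- function(x, ...) {
  cat(sprintf("<rob_table> %d stud%s, 7 domains%s\n", nrow(x),
              if (nrow(x) == 1) "y" else "ies",
              if ("overall" %in% names(x)) " + consensus overall" else ""))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
print.rob_classification <- function(x, ...) {
  n <- count_by_level(x)
  cat(sprintf("<rob_classification> %d studies (%s)\n", nrow(x),
              paste(sprintf("%s %d", names(n), n), collapse = ", ")))
  if (!is.null(x$concordant))
    cat(sprintf("  concordance with consensus: %d/%d\n",
                sum(x$concordant), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}
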