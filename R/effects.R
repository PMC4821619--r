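#' Study-level effect sets
#'
#' An *effect set* is the unit of pooling: one row per study x outcome x
#' exposure, carrying a ratio-scale relative-risk estimate (OR, HR, RR, IRR
#' or ReR -- treated interchangeably on the log scale) together with its
#' confidence interval and the study's design stratum (cohort or
#' case-control). `effect_set()` validates a data frame against the schema
#' and stamps it with class `"effect_set"`.
#'
#' Validation enforces, per row: positive estimate and CI bounds;
#' `ci_low <= estimate <= ci_high` up to one unit in the last printed
#' decimal (inputs transcribed from published tables are rounded, so e.g.
#' 1.06 is allowed to sit 0.01 outside its printed bounds); `ci_level`
#' strictly inside (0, 1); and uniqueness of
#' `(study_id, outcome, exposure)`.
#'
#' @param x A data frame with columns `study_id`, `design` (`"cohort"` or
#'   `"case_control"`), `measure` (`"OR"`, `"HR"`, `"RR"`, `"IRR"`,
#'   `"ReR"`), `outcome`, `exposure`, `estimate`, `ci_low`, `ci_high`, and
#'   optionally `ci_level` (default 0.95) and `adjusted` (default `TRUE`).
#' @param label Optional label describing the set (e.g. an outcome name).
#' @return A data frame of class `"effect_set"`.
#' @seealso [read_effects_csv()], [load_fixture()], [pool_by_subgroup()]
#' @examples
#' es <- effect_set(data.frame(
#'   study_id = "graham_2010", design = "cohort", measure = "HR",
#'   outcome = "myocardial_infarction",
#'   exposure = "rosiglitazone_vs_pioglitazone",
#'   estimate = 1.06, ci_low = 0.96, ci_high = 1.18))
#' @export
effect_set <- function(x, label = NULL) {
  required <- c("study_id", "design", "measure", "outcome", "exposure",
                "estimate", "ci_low", "ci_high")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    .stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$ci_level)) x$ci_level <- rep(0.95, nrow(x))
  if (is.null(x$adjusted)) x$adjusted <- rep(TRUE, nrow(x))
  x$adjusted <- as.logical(x$adjusted)
  for (col in c("study_id", "design", "measure", "outcome", "exposure"))
    x[[col]] <- as.character(x[[col]])

  if (nrow(x)) .validate_effect_rows(x)
  rownames(x) <- NULL
  structure(x[, c(required, "ci_level", "adjusted")],
            label = label, class = c("effect_set", "data.frame"))
}

.effect_measures <- c("OR", "HR", "RR", "IRR", "ReR")
.effect_designs  <- c("cohort", "case_control")

.validate_effect_rows <- function(x) {
  bad <- function(cond, what) {
    if (any(cond))
      .stopf("%s in row(s) %s", what, paste(which(cond), collapse = ", "))
  }
  bad(!x$design %in% .effect_designs,
      sprintf("design must be one of %s", paste(.effect_designs, collapse = "/")))
  bad(!x$measure %in% .effect_measures,
      sprintf("measure must be one of %s", paste(.effect_measures, collapse = "/")))
  num <- c("estimate", "ci_low", "ci_high")
  for (col in num) {
    bad(!is.finite(x[[col]]), sprintf("non-numeric %s", col))
    bad(x[[col]] <= 0, sprintf("non-positive %s", col))
  }
  bad(!is.finite(x$ci_level) | x$ci_level <= 0 | x$ci_level >= 1,
      "ci_level outside (0, 1)")
  tol_lo <- .print_unit(x$ci_low)
  tol_hi <- .print_unit(x$ci_high)
  bad(x$ci_low > x$estimate + tol_lo | x$estimate > x$ci_high + tol_hi,
      "estimate outside its own confidence interval")
  key <- paste(x$study_id, x$outcome, x$exposure, sep = "\r")
  bad(duplicated(key) | duplicated(key, fromLast = TRUE),
      "duplicate (study_id, outcome, exposure)")
  invisible(x)
}

#' Read or write an effect-set CSV
#'
#' The interchange format is a UTF-8, comma-separated, decimal-point CSV
#' with a header row:
#' `study_id,design,measure,outcome,exposure,estimate,ci_low,ci_high[,ci_level,adjusted]`.
#' Rows failing validation abort the read with their row numbers.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector remapping file column
#'   names onto the schema, e.g. `c(study_id = "id")` when the file calls
#'   the study column `id`.
#' @param label Optional label passed to [effect_set()].
#' @return `read_effects_csv()` returns an [effect_set()];
#'   `write_effects_csv()` invisibly returns `path`.
#' @export
read_effects_csv <- function(path, schema = NULL, label = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    if (is.null(names(schema)) || any(names(schema) == ""))
      .stopf("`schema` must be a named character vector (schema name = file column)")
    missing_src <- setdiff(unname(schema), names(x))
    if (length(missing_src))
      .stopf("schema refers to absent column(s): %s", paste(missing_src, collapse = ", "))
    names(x)[match(schema, names(x))] <- names(schema)
  }
  effect_set(x, label = label %||% sub("\\.csv$", "", basename(path)))
}

#' @param set An [effect_set()].
#' @rdname read_effects_csv
#' @export
write_effects_csv <- function(set, path) {
  stopifnot(inherits(set, "effect_set"))
  write.csv(as.data.frame(set), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an effect set or RoB table as JSON
#'
#' Mirrors the CSV schemas row-for-row; numbers are written at full
#' precision.
#'
#' @param x An [effect_set()] or RoB table ([read_rob_csv()]).
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return A JSON string (invisibly, when `path` is given).
#' @export
to_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(as.data.frame(x), dataframe = "rows",
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Load a packaged fixture
#'
#' Four plain-CSV fixtures encode the study-level inputs of the two
#' re-analysed reviews: `"tzd_effects"` (31 estimates from 16 studies of
#' rosiglitazone vs pioglitazone: 15 myocardial infarction, 9 heart
#' failure, 7 overall mortality), `"cox2_effects"` (66 estimates from 20
#' studies of individual NSAIDs vs no NSAID), and the matching consensus
#' domain-judgment tables `"tzd_rob"` (16 profiles) and `"cox2_rob"` (21
#' profiles; one study contributes a RoB profile but no printed per-drug
#' estimate).
#'
#' @param name One of `"tzd_effects"`, `"cox2_effects"`, `"tzd_rob"`,
#'   `"cox2_rob"`.
#' @return An [effect_set()] for `*_effects`, a RoB table (see
#'   [read_rob_csv()]) for `*_rob`.
#' @examples
#' tzd <- load_fixture("tzd_effects")
#' table(tzd$outcome)
#' @export
load_fixture <- function(name = c("tzd_effects", "cox2_effects",
                                  "tzd_rob", "cox2_rob")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "robmeta",
                      mustWork = TRUE)
  if (grepl("_rob$", name)) read_rob_csv(path) else
    read_effects_csv(path, label = name)
}

#' @export
print.effect_set <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("<effect_set%s> %d effect(s), %d stud%s\n",
              if (is.null(lbl)) "" else paste0(": ", lbl),
              nrow(x), length(unique(x$study_id)),
              if (length(unique(x$study_id)) == 1) "y" else "ies"))
  print(as.data.frame(x), ...)
  invisible(x)
}

# Subsetting an effect_set keeps its class and label.
#' @export
`[.effect_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("study_id", "estimate", "ci_low", "ci_high")
                                %in% names(out))) {
    class(out) <- c("effect_set", "data.frame")
    attr(out, "label") <- attr(x, "label")
  }
  out
}
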