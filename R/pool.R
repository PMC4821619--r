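#' Convert ratio-scale effects to log effects with standard errors
#'
#' The generic inverse-variance method works on the natural-log scale:
#' `y = ln(estimate)` and, for a symmetric z-based interval,
#' `se = (ln(ci_high) - ln(ci_low)) / (2 * z)` with `z` the standard
#' normal quantile for the interval's level (1.959964 at 95%). This
#' back-calculation is exact for Wald-type intervals and is the standard
#' way to recover a usable variance when only the published point
#' estimate and CI are available.
#'
#' @param set An [effect_set()] (any number of rows).
#' @return A data frame with columns `study_id`, `design`, `y`, `se`.
#' @examples
#' es <- load_fixture("tzd_effects")
#' to_log_effect(es[es$study_id == "graham_2010" &
#'                  es$outcome == "myocardial_infarction", ])
#' @export
to_log_effect <- function(set) {
  stopifnot(inherits(set, "effect_set"))
  if (nrow(set) && any(set$ci_high == set$ci_low))
    .stopf("zero-width confidence interval in row(s) %s: se undefined",
           paste(which(set$ci_high == set$ci_low), collapse = ", "))
  data.frame(study_id = set$study_id,
             design = set$design,
             y = log(set$estimate),
             se = (log(set$ci_high) - log(set$ci_low)) /
               (2 * z_quantile(set$ci_level)),
             stringsAsFactors = FALSE)
}

.check_log_effects <- function(le) {
  if (!is.data.frame(le) || !all(c("study_id", "y", "se") %in% names(le)))
    .stopf("log effects must be a data frame with study_id, y, se (see to_log_effect())")
  if (nrow(le) == 0L) .stopf("cannot pool an empty set of effects")
  if (any(!is.finite(le$se) | le$se <= 0)) .stopf("all standard errors must be positive")
  le
}

.pooled_result <- function(le, w, tau2, Q, ci_level, method) {
  k <- nrow(le)
  pooled_log <- sum(w * le$y) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  z <- z_quantile(ci_level)
  structure(list(
    k = k,
    pooled_log = pooled_log,
    se_pooled = se_pooled,
    estimate = exp(pooled_log),
    ci_low = exp(pooled_log - z * se_pooled),
    ci_high = exp(pooled_log + z * se_pooled),
    ci_level = ci_level,
    Q = Q, df = k - 1L,
    tau2 = tau2,
    i2 = i_squared(Q, k - 1L),
    weights = setNames(w / sum(w), le$study_id),
    method = method), class = "pooled_result")
}

#' Fixed-effect (common-effect) inverse-variance pooling
#'
#' Weights `w_i = 1/se_i^2`; the pooled log effect is the weighted mean,
#' its standard error `(sum w_i)^(-1/2)`, and Cochran's
#' `Q = sum w_i (y_i - pooled)^2`. `tau2` is 0 by definition of the
#' model.
#'
#' @param le Log effects from [to_log_effect()] (columns `study_id`, `y`,
#'   `se`).
#' @param ci_level Confidence level for the pooled interval.
#' @return A `"pooled_result"`: list with `k`, `pooled_log`, `se_pooled`,
#'   `estimate`, `ci_low`, `ci_high`, `Q`, `df`, `tau2`, `i2`, and
#'   normalized `weights`.
#' @export
fixed_effect_pool <- function(le, ci_level = 0.95) {
  le <- .check_log_effects(le)
  w <- 1 / le$se^2
  mu <- sum(w * le$y) / sum(w)
  Q <- if (nrow(le) == 1L) 0 else sum(w * (le$y - mu)^2)
  .pooled_result(le, w, tau2 = 0, Q = Q, ci_level = ci_level, method = "fixed")
}

#' DerSimonian-Laird moment estimate of the between-study variance
#'
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with `w` the
#' fixed-effect weights. Truncation at zero is part of the estimator.
#' With fewer than two studies the between-study variance is not
#' estimable and 0 is returned with a warning.
#'
#' @inheritParams fixed_effect_pool
#' @return A single non-negative number.
#' @export
dl_tau2 <- function(le) {
  le <- .check_log_effects(le)
  if (nrow(le) < 2L) {
    .warnf("tau2 is not estimable from %d study; returning 0", nrow(le))
    return(0)
  }
  w <- 1 / le$se^2
  mu <- sum(w * le$y) / sum(w)
  Q <- sum(w * (le$y - mu)^2)
  max(0, (Q - (nrow(le) - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Random-effects weights `w*_i = 1/(se_i^2 + tau2)` with `tau2` from
#' [dl_tau2()]; the pooled log effect, its standard error and the
#' exponentiated z-based CI follow as in [fixed_effect_pool()] under the
#' starred weights. Heterogeneity statistics (`Q`, `i2`) are always
#' computed from the *fixed-effect* weights -- the standard definition,
#' independent of the pooling model. When `tau2 = 0` the result
#' coincides with the fixed-effect pool.
#'
#' @inheritParams fixed_effect_pool
#' @return A `"pooled_result"`; see [fixed_effect_pool()].
#' @examples
#' tzd <- load_fixture("tzd_effects")
#' mi <- tzd[tzd$outcome == "myocardial_infarction", ]
#' random_effects_pool(to_log_effect(mi))
#' @export
random_effects_pool <- function(le, ci_level = 0.95) {
  le <- .check_log_effects(le)
  w_fixed <- 1 / le$se^2
  mu_fixed <- sum(w_fixed * le$y) / sum(w_fixed)
  Q <- if (nrow(le) == 1L) 0 else sum(w_fixed * (le$y - mu_fixed)^2)
  tau2 <- if (nrow(le) < 2L) 0 else
    max(0, (Q - (nrow(le) - 1)) / (sum(w_fixed) - sum(w_fixed^2) / sum(w_fixed)))
  w <- 1 / (le$se^2 + tau2)
  .pooled_result(le, w, tau2 = tau2, Q = Q, ci_level = ci_level,
                 method = "random")
}

#' I-squared heterogeneity percentage
#'
#' `I2 = 100 * max(0, (Q - df) / Q)`, the share of total variability in
#' the effect estimates attributable to between-study heterogeneity
#' rather than sampling error; 0 when `Q = 0`.
#'
#' @param Q Cochran's heterogeneity statistic (>= 0).
#' @param df Its degrees of freedom, `k - 1` (>= 0).
#' @return A percentage in `[0, 100]`.
#' @export
i_squared <- function(Q, df) {
  if (any(df < 0)) .stopf("df must be non-negative")
  if (any(Q < 0)) .stopf("Q must be non-negative")
  ifelse(Q > 0, 100 * pmax(0, (Q - df) / Q), 0)
}

#' Pool an effect set within design strata and overall
#'
#' Runs [random_effects_pool()] (or [fixed_effect_pool()]) independently
#' inside each design stratum -- each stratum gets its own between-study
#' variance -- and once more on the union of all studies for the overall
#' synthesis, which therefore also carries its own single `tau2` rather
#' than being a combination of the stratum results. Strata with no
#' studies are omitted from `per_group` (the "not applicable" cells of a
#' stratified report).
#'
#' @param set An [effect_set()]; every row must carry a `design`.
#' @param model `"random"` (default) or `"fixed"`.
#' @param ci_level Confidence level.
#' @return A `"subgroup_result"`: list with `per_group` (named list of
#'   `"pooled_result"` per design present) and `overall`.
#' @examples
#' tzd <- load_fixture("tzd_effects")
#' pool_by_subgroup(tzd[tzd$outcome == "myocardial_infarction", ])
#' @export
pool_by_subgroup <- function(set, model = c("random", "fixed"),
                             ci_level = 0.95) {
  stopifnot(inherits(set, "effect_set"))
  model <- match.arg(model)
  if (nrow(set) == 0L) .stopf("cannot pool an empty effect set")
  pool <- if (model == "random") random_effects_pool else fixed_effect_pool
  le <- to_log_effect(set)
  per_group <- lapply(split(le, factor(le$design, levels = .effect_designs)),
                      function(g) if (nrow(g)) pool(g, ci_level) else NULL)
  per_group <- Filter(Negate(is.null), per_group)
  structure(list(per_group = per_group,
                 overall = pool(le, ci_level),
                 label = attr(set, "label"),
                 model = model),
            class = "subgroup_result")
}

#' @export
print.pooled_result <- function(x, digits = 2, ...) {
  cat(sprintf("%s-effects inverse-variance pool, k = %d\n",
              if (x$method == "random") "Random" else "Fixed", x$k))
  cat(sprintf("  %s (%d%% CI %s-%s)\n",
              format(round(x$estimate, digits), nsmall = digits),
              round(100 * x$ci_level),
              format(round(x$ci_low, digits), nsmall = digits),
              format(round(x$ci_high, digits), nsmall = digits)))
  cat(sprintf("  Q = %.2f (df = %d), tau2 = %.4f, I2 = %.0f%%\n",
              x$Q, x$df, x$tau2, x$i2))
  invisible(x)
}

#' @export
print.subgroup_result <- function(x, ...) {
  lbl <- x$label
  cat(sprintf("<subgroup_result%s>\n",
              if (is.null(lbl)) "" else paste0(": ", lbl)))
  for (g in names(x$per_group)) {
    cat(sprintf("-- %s --\n", g))
    print(x$per_group[[g]], ...)
  }
  cat("-- overall --\n")
  print(x$overall, ...)
  invisible(x)
}
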