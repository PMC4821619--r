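#' Simulate an effect set with known truth
#'
#' Generates study-level relative risks with the structure the
#' random-effects model assumes. For each study: an overall RoB level is
#' drawn from `level_probs`; the study-specific true log effect is
#' `theta_i ~ Normal(mu + bias_shift[level], tau2)`; the sampling
#' standard error `se_i` is uniform on `se_range`; the observed log
#' effect is `y_i ~ Normal(theta_i, se_i^2)`; and the emitted row carries
#' `estimate = exp(y_i)` with the z-based 95% CI `exp(y_i +/- z se_i)`.
#' The bias mechanism -- an additive log-scale shift attached to
#' higher-RoB studies -- is the simplest structure under which excluding
#' those studies should move the pooled estimate back toward `mu`.
#'
#' Defaults describe a realistic review: `se_range` spans the standard
#' errors observed in the packaged fixtures, and `level_probs` and
#' `design_prob` match the empirical mix of the 37 fixture studies
#' (8 low / 18 moderate / 9 serious / 2 critical; 17 cohorts).
#'
#' @param k Number of studies.
#' @param mu True log relative risk.
#' @param tau2 Between-study variance of the log effects (>= 0).
#' @param se_range Length-2 positive range for per-study SEs.
#' @param design_prob Probability a study is a cohort (vs case-control).
#' @param bias_shift Named numeric, additive log-scale bias per RoB level.
#' @param level_probs Named probabilities over [rob_levels()], summing
#'   to 1.
#' @param seed Integer seed; the same seed reproduces the same set.
#' @return An [effect_set()] with one row per study and a `truth`
#'   attribute: list with `mu`, `tau2`, `levels` (named study -> level,
#'   usable as a classification), `theta`, `y`, `se`.
#' @examples
#' es <- simulate_effect_set(k = 20, mu = log(1.2), tau2 = 0.05, seed = 1)
#' random_effects_pool(to_log_effect(es))
#' @export
simulate_effect_set <- function(k,
                                mu = log(1.2),
                                tau2 = 0,
                                se_range = c(0.05, 0.35),
                                design_prob = 17 / 37,
                                bias_shift = c(low = 0, moderate = 0,
                                               serious = 0, critical = 0),
                                level_probs = c(low = 8, moderate = 18,
                                                serious = 9, critical = 2) / 37,
                                seed = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) .stopf("`k` must be >= 1")
  if (tau2 < 0) .stopf("`tau2` must be non-negative")
  if (length(se_range) != 2L || any(se_range <= 0) || diff(se_range) < 0)
    .stopf("`se_range` must be a positive, non-decreasing length-2 range")
  if (abs(sum(level_probs) - 1) > 1e-8 || any(level_probs < 0) ||
      !setequal(names(level_probs), rob_levels()))
    .stopf("`level_probs` must be named over rob_levels() and sum to 1")
  if (!setequal(names(bias_shift), rob_levels()))
    .stopf("`bias_shift` must be named over rob_levels()")
  k <- as.integer(k)

  with_seed(seed, {
    study_id <- sprintf("study_%03d", seq_len(k))
    levels_i <- sample(rob_levels(), k, replace = TRUE,
                       prob = level_probs[rob_levels()])
    theta <- rnorm(k, mu + unname(bias_shift[levels_i]), sqrt(tau2))
    se <- runif(k, se_range[1], se_range[2])
    y <- rnorm(k, theta, se)
    z <- z_quantile(0.95)
    set <- effect_set(data.frame(
      study_id = study_id,
      design = ifelse(rbinom(k, 1, design_prob) == 1, "cohort", "case_control"),
      measure = "RR",
      outcome = "synthetic_outcome",
      exposure = "synthetic_exposure",
      estimate = exp(y),
      ci_low = exp(y - z * se),
      ci_high = exp(y + z * se),
      stringsAsFactors = FALSE), label = "simulated")
    attr(set, "truth") <- list(mu = mu, tau2 = tau2,
                               levels = setNames(levels_i, study_id),
                               theta = theta, y = y, se = se)
    set
  })
}

#' Simulate paired ordinal ratings with controllable agreement
#'
#' With probability `agreement_boost` the two raters are forced to agree
#' (one draw from `marginal` copied to both); otherwise each rates
#' independently from `marginal`. `agreement_boost = 0` is the
#' chance-agreement null (kappa ~ 0); `agreement_boost = 1` gives perfect
#' agreement (kappa = 1 whenever two categories appear).
#'
#' @param n Number of rated units.
#' @param marginal Named probabilities over `categories`, summing to 1.
#' @param agreement_boost Probability in `[0, 1]` of forced agreement.
#' @param categories Ordered category set (defaults to [rob_levels()]).
#' @param seed Integer seed.
#' @return A data frame with `unit_id`, `rater1`, `rater2`.
#' @export
simulate_rating_pairs <- function(n,
                                  marginal = c(low = 8, moderate = 18,
                                               serious = 9, critical = 2) / 37,
                                  agreement_boost = 0,
                                  categories = rob_levels(),
                                  seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) .stopf("`n` must be >= 1")
  if (agreement_boost < 0 || agreement_boost > 1)
    .stopf("`agreement_boost` must lie in [0, 1]")
  if (abs(sum(marginal) - 1) > 1e-8 || any(marginal < 0) ||
      !setequal(names(marginal), categories))
    .stopf("`marginal` must be named over `categories` and sum to 1")
  n <- as.integer(n)

  with_seed(seed, {
    p <- marginal[categories]
    r1 <- sample(categories, n, replace = TRUE, prob = p)
    r2 <- sample(categories, n, replace = TRUE, prob = p)
    forced <- runif(n) < agreement_boost
    r2[forced] <- r1[forced]
    data.frame(unit_id = sprintf("unit_%05d", seq_len(n)),
               rater1 = r1, rater2 = r2, stringsAsFactors = FALSE)
  })
}

#' Simulate RoB domain-judgment profiles
#'
#' Independent draws per domain from per-domain level distributions;
#' used to exercise [aggregate_overall()] across the full space of
#' profiles (monotonicity, escalation containment).
#'
#' @param n Number of studies.
#' @param domain_level_probs Either a single named probability vector
#'   over [rob_levels()] applied to every domain, or a named list with
#'   one such vector per key of [rob_domains()].
#' @param seed Integer seed.
#' @return A `"rob_table"` (without a consensus `overall` column).
#' @export
simulate_rob_profiles <- function(n,
                                  domain_level_probs = c(low = 0.55,
                                                         moderate = 0.3,
                                                         serious = 0.1,
                                                         critical = 0.05),
                                  seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) .stopf("`n` must be >= 1")
  if (!is.list(domain_level_probs))
    domain_level_probs <- setNames(rep(list(domain_level_probs),
                                       length(rob_domains())), rob_domains())
  if (!setequal(names(domain_level_probs), rob_domains()))
    .stopf("`domain_level_probs` must cover exactly the 7 domains")
  for (d in rob_domains()) {
    p <- domain_level_probs[[d]]
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0) ||
        !setequal(names(p), rob_levels()))
      .stopf("probabilities for domain %s must be named over rob_levels() and sum to 1", d)
  }
  n <- as.integer(n)

  with_seed(seed, {
    cols <- lapply(rob_domains(), function(d) {
      p <- domain_level_probs[[d]][rob_levels()]
      sample(rob_levels(), n, replace = TRUE, prob = p)
    })
    names(cols) <- rob_domains()
    rob_table(data.frame(study_id = sprintf("study_%03d", seq_len(n)),
                         cols, stringsAsFactors = FALSE))
  })
}
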