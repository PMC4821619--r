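#' Linear agreement weights for ordinal categories
#'
#' `w[i, j] = 1 - |i - j| / (k - 1)`: full credit on the diagonal,
#' partial credit decaying linearly with the distance between the two
#' ratings, zero in the extreme corners. This is the *agreement*
#' convention (diagonal 1); the complementary disagreement weighting
#' yields the identical kappa.
#'
#' @param k Number of ordered categories (>= 2).
#' @return A symmetric `k x k` matrix.
#' @examples
#' linear_weights(4)
#' @export
linear_weights <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 2)
    .stopf("`k` must be a single integer >= 2")
  k <- as.integer(k)
  i <- seq_len(k)
  1 - abs(outer(i, i, "-")) / (k - 1)
}

#' Linearly weighted Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two raters on a common ordered
#' category set: `kappa = (p_obs - p_exp) / (1 - p_exp)` where the
#' observed and expected agreement are weighted sums of the contingency
#' proportions and of the marginal products under [linear_weights()].
#' The contingency table is built over the *full declared* category set:
#' categories never used by either rater keep their zero rows/columns,
#' which affects the marginals and is therefore an explicit choice (the
#' default category set is the four RoB levels).
#'
#' Both raters constant on the same single category gives expected
#' agreement 1, for which kappa is undefined -- this errors rather than
#' returning 1.
#'
#' @param rater1,rater2 Character vectors of ratings (same length), or a
#'   data frame with columns `rater1` and `rater2` passed as the first
#'   argument.
#' @param categories Ordered category set both ratings are drawn from.
#' @param n_boot Number of bootstrap resamples (over units) for an
#'   optional percentile CI on kappa; 0 (default) skips it.
#' @param ci_level Level for the bootstrap interval.
#' @param seed Seed for the bootstrap resampling.
#' @return An `"agreement_result"`: list with `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n`, `k`, `contingency`
#'   (k x k counts, rater1 in rows), `categories`, and `boot_ci` when
#'   requested.
#' @examples
#' weighted_kappa(c("low", "low", "serious"),
#'                c("low", "moderate", "serious"))
#' @export
weighted_kappa <- function(rater1, rater2 = NULL, categories = rob_levels(),
                           n_boot = 0L, ci_level = 0.95, seed = NULL) {
  if (is.data.frame(rater1)) {
    if (!all(c("rater1", "rater2") %in% names(rater1)))
      .stopf("rating data frame needs `rater1` and `rater2` columns")
    rater2 <- rater1$rater2
    rater1 <- rater1$rater1
  }
  if (length(rater1) != length(rater2))
    .stopf("rater1 and rater2 must have the same length")
  n <- length(rater1)
  if (n < 1L) .stopf("at least one rating pair is required")
  if (length(categories) < 2L || anyDuplicated(categories))
    .stopf("`categories` must be >= 2 distinct ordered categories")
  outside <- setdiff(c(rater1, rater2), categories)
  if (length(outside))
    .stopf("rating outside the declared category set: %s",
           paste(outside, collapse = ", "))

  f1 <- factor(rater1, levels = categories)
  f2 <- factor(rater2, levels = categories)
  contingency <- table(rater1 = f1, rater2 = f2)
  res <- .kappa_from_table(contingency)
  if (is.na(res$kappa))
    .stopf("kappa undefined: both raters constant on \"%s\" (expected agreement 1)",
           rater1[1])

  out <- structure(c(res, list(n = n, k = length(categories),
                               contingency = contingency,
                               categories = categories)),
                   class = "agreement_result")
  if (n_boot > 0L) {
    out$boot_ci <- with_seed(seed, {
      ks <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        .kappa_from_table(table(rater1 = f1[idx], rater2 = f2[idx]))$kappa
      }, numeric(1))
      unname(stats::quantile(ks, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                             na.rm = TRUE, names = FALSE))
    })
  }
  out
}

.kappa_from_table <- function(contingency) {
  p <- contingency / sum(contingency)
  w <- linear_weights(nrow(p))
  observed <- sum(w * p)
  expected <- sum(w * outer(rowSums(p), colSums(p)))
  kappa <- if (expected >= 1 - 1e-12) NA_real_ else
    (observed - expected) / (1 - expected)
  list(kappa = kappa, observed_agreement = observed,
       expected_agreement = expected)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Linearly weighted kappa: %.4f (n = %d, %d categories)\n",
              x$kappa, x$n, x$k))
  cat(sprintf("  observed agreement %.4f, expected %.4f\n",
              x$observed_agreement, x$expected_agreement))
  if (!is.null(x$boot_ci))
    cat(sprintf("  bootstrap CI (%.4f, %.4f)\n", x$boot_ci[1], x$boot_ci[2]))
  invisible(x)
}
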