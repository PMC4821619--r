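# Independent oracle: direct-summation inverse-variance pooling, written
# against the defining formulas only, used to cross-check the vectorized
# implementation.
oracle_pool <- function(y, se, random = TRUE) {
  k <- length(y)
  w <- numeric(k); for (i in 1:k) w[i] <- 1 / se[i]^2
  sw <- 0; swy <- 0
  for (i in 1:k) { sw <- sw + w[i]; swy <- swy + w[i] * y[i] }
  mu_f <- swy / sw
  Q <- 0; for (i in 1:k) Q <- Q + w[i] * (y[i] - mu_f)^2
  tau2 <- 0
  if (random && k >= 2) {
    sw2 <- 0; for (i in 1:k) sw2 <- sw2 + w[i]^2
    tau2 <- max(0, (Q - (k - 1)) / (sw - sw2 / sw))
  }
  ws <- numeric(k); for (i in 1:k) ws[i] <- 1 / (se[i]^2 + tau2)
  sws <- 0; swsy <- 0
  for (i in 1:k) { sws <- sws + ws[i]; swsy <- swsy + ws[i] * y[i] }
  list(pooled_log = swsy / sws, se_pooled = 1 / sqrt(sws), Q = Q, tau2 = tau2)
}

test_that("log-effect back-calculation matches hand-computed values", {
  graham <- make_effects(1.06, 0.96, 1.18, measure = "HR")
  le <- to_log_effect(graham)
  expect_equal(le$y, log(1.06))
  expect_equal(le$se, (log(1.18) - log(0.96)) / (2 * 1.959964),
               tolerance = 1e-6)
  expect_equal(round(le$y, 4), 0.0583)
  expect_equal(round(le$se, 4), 0.0526)

  dormuth <- make_effects(1.00, 0.67, 1.49)
  le2 <- to_log_effect(dormuth)
  expect_equal(le2$y, 0)
  expect_equal(round(le2$se, 4), 0.2039)

  # exp(y +/- z se) reproduces the source CI within printed rounding
  z <- qnorm(0.975)
  expect_equal(exp(le$y + c(-1, 1) * z * le$se), c(0.96, 1.18),
               tolerance = 0.01)

  expect_error(to_log_effect(make_effects(1.0, 1.0, 1.0)), "zero-width")
})

test_that("fixed-effect pooling follows the closed form", {
  one <- fixed_effect_pool(make_log_effects(0.3, 0.12))
  expect_equal(one$pooled_log, 0.3)
  expect_equal(one$se_pooled, 0.12)
  expect_equal(one$Q, 0)
  expect_identical(one$df, 0L)
  expect_equal(one$tau2, 0)
  expect_equal(one$i2, 0)

  two <- fixed_effect_pool(make_log_effects(c(0, 0.2), c(0.1, 0.1)))
  expect_equal(two$pooled_log, 0.1)
  expect_equal(two$Q, 2.0)
  expect_equal(sum(two$weights), 1)

  same <- fixed_effect_pool(make_log_effects(rep(0.15, 4), rep(0.2, 4)))
  expect_equal(same$Q, 0)
  expect_error(fixed_effect_pool(make_log_effects(numeric(0), numeric(0))),
               "empty")
  expect_error(fixed_effect_pool(make_log_effects(0.1, 0)), "positive")
})

test_that("DerSimonian-Laird tau2 matches the moment formula with truncation", {
  le <- make_log_effects(c(0, 0.4), c(0.1, 0.1))
  expect_equal(dl_tau2(le), 0.07)  # (8 - 1) / (200 - 100)
  expect_equal(dl_tau2(make_log_effects(c(0.1, 0.12), c(0.2, 0.2))), 0)
  expect_warning(t1 <- dl_tau2(make_log_effects(0.3, 0.1)), "not estimable")
  expect_equal(t1, 0)
})

test_that("random-effects pooling reduces to fixed-effect when tau2 = 0", {
  le <- make_log_effects(c(0.1, 0.12, 0.11), c(0.2, 0.25, 0.22))
  expect_equal(dl_tau2(le), 0)
  re <- random_effects_pool(le)
  fe <- fixed_effect_pool(le)
  expect_equal(re$pooled_log, fe$pooled_log)
  expect_equal(re$se_pooled, fe$se_pooled)
  expect_equal(re$weights, fe$weights)

  # k = 1: pooled result equals the single study
  single <- random_effects_pool(make_log_effects(0.25, 0.1))
  expect_equal(single$pooled_log, 0.25)
  expect_equal(single$tau2, 0)
  expect_equal(single$i2, 0)
})

test_that("pooling agrees with a direct-summation oracle for small k", {
  set.seed(1203)
  for (k in 2:4) {
    for (rep in 1:25) {
      y <- rnorm(k, 0.1, 0.3)
      se <- runif(k, 0.05, 0.4)
      got <- random_effects_pool(make_log_effects(y, se))
      want <- oracle_pool(y, se)
      expect_equal(got$pooled_log, want$pooled_log, tolerance = 1e-12)
      expect_equal(got$se_pooled, want$se_pooled, tolerance = 1e-12)
      expect_equal(got$Q, want$Q, tolerance = 1e-12)
      expect_equal(got$tau2, want$tau2, tolerance = 1e-12)
    }
  }
})

test_that("pooling agrees with metafor's DL implementation on the fixtures", {
  requireNamespace("metafor", quietly = TRUE)
  tzd <- load_fixture("tzd_effects")
  cox <- load_fixture("cox2_effects")
  sets <- list(tzd[tzd$outcome == "myocardial_infarction", ],
               tzd[tzd$outcome == "heart_failure", ],
               cox[cox$exposure == "ibuprofen", ],
               cox[cox$exposure == "naproxen", ])
  for (set in sets) {
    le <- to_log_effect(set)
    got <- random_effects_pool(le)
    ref <- metafor::rma(yi = le$y, sei = le$se, method = "DL")
    expect_equal(got$pooled_log, as.numeric(ref$b), tolerance = 1e-10)
    expect_equal(got$se_pooled, ref$se, tolerance = 1e-10)
    expect_equal(got$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(got$i2, ref$I2, tolerance = 1e-6)
  }
})

test_that("I-squared follows its closed form with truncation", {
  expect_equal(i_squared(10, 5), 50)
  expect_equal(i_squared(3, 5), 0)
  expect_equal(i_squared(0, 0), 0)
  expect_error(i_squared(1, -1), "non-negative")
  expect_error(i_squared(-1, 1), "non-negative")
})

test_that("multiplying all ratios by a constant shifts the log pool only", {
  set.seed(88)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    y <- rnorm(k, 0.2, 0.3); se <- runif(k, 0.05, 0.35)
    z <- qnorm(0.975)
    base <- make_effects(exp(y), exp(y - z * se), exp(y + z * se))
    scaled <- make_effects(2.5 * exp(y), 2.5 * exp(y - z * se),
                           2.5 * exp(y + z * se))
    a <- random_effects_pool(to_log_effect(base))
    b <- random_effects_pool(to_log_effect(scaled))
    expect_equal(b$pooled_log - a$pooled_log, log(2.5), tolerance = 1e-10)
    expect_equal(b$se_pooled, a$se_pooled, tolerance = 1e-10)
    expect_equal(b$Q, a$Q, tolerance = 1e-8)
    expect_equal(b$tau2, a$tau2, tolerance = 1e-10)
    expect_equal(b$i2, a$i2, tolerance = 1e-8)
  }
})

test_that("study order never changes any pooled output", {
  tzd <- load_fixture("tzd_effects")
  mi <- tzd[tzd$outcome == "myocardial_infarction", ]
  le <- to_log_effect(mi)
  a <- random_effects_pool(le)
  set.seed(5)
  b <- random_effects_pool(le[sample(nrow(le)), ])
  expect_equal(a$pooled_log, b$pooled_log)
  expect_equal(a$Q, b$Q)
  expect_equal(a$tau2, b$tau2)
  expect_equal(a$weights[names(a$weights)], b$weights[names(a$weights)])
})

test_that("subgroup pooling strata are independent and the overall is a single synthesis", {
  tzd <- load_fixture("tzd_effects")
  mi <- tzd[tzd$outcome == "myocardial_infarction", ]
  sub <- pool_by_subgroup(mi)
  expect_named(sub$per_group, c("cohort", "case_control"))
  expect_identical(sub$overall$k,
                   sub$per_group$cohort$k + sub$per_group$case_control$k)
  # overall re-estimates one tau2 on the union, not a combination of strata
  expect_equal(sub$overall$pooled_log,
               random_effects_pool(to_log_effect(mi))$pooled_log)

  # a stratum with no studies is omitted (meloxicam: case-control only)
  cox <- load_fixture("cox2_effects")
  mel <- pool_by_subgroup(cox[cox$exposure == "meloxicam", ])
  expect_named(mel$per_group, "case_control")
  expect_identical(mel$overall$k, 2L)
  expect_equal(mel$overall$pooled_log, mel$per_group$case_control$pooled_log)
})
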