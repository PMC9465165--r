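test_that("hazard closed forms match their definitions", {
  expect_equal(hazard(hazard_spec("constant", 0.098), 6), 0.098)
  expect_equal(hazard(hazard_spec("gompertz", 0.098, 0), 17), 0.098)
  expect_equal(hazard(hazard_spec("weibull", 2, 1), 3), 6)
  expect_error(hazard_spec("constant", -1), "positive")
  expect_error(hazard_spec("weibull", 0.1, -1.2), "> -1")
  expect_error(hazard(hazard_spec("weibull", 0.1, -0.5), 0), "undefined at t = 0")
})

test_that("cumulative hazard agrees with numerical quadrature of the hazard", {
  expect_equal(cumulative_hazard(hazard_spec("constant", 0.098), 0, 12), 1.176)
  set.seed(11)
  for (i in 1:12) {
    fam <- sample(c("constant", "gompertz", "weibull"), 1)
    spec <- hazard_spec(fam, runif(1, 0.02, 0.5), runif(1, -0.5, 0.5))
    t0 <- runif(1, 0.1, 5); t1 <- t0 + runif(1, 0.5, 30)
    quad <- integrate(function(u) hazard(spec, u), t0, t1,
                      rel.tol = 1e-10)$value
    expect_equal(cumulative_hazard(spec, t0, t1), quad, tolerance = 1e-6)
    # additive over adjoining intervals, zero on empty intervals
    tm <- (t0 + t1) / 2
    expect_equal(cumulative_hazard(spec, t0, tm) + cumulative_hazard(spec, tm, t1),
                 cumulative_hazard(spec, t0, t1), tolerance = 1e-12)
    expect_identical(cumulative_hazard(spec, t1, t1), 0)
  }
})

test_that("Gompertz near-zero shape matches quadrature (series branch)", {
  spec <- hazard_spec("gompertz", 0.1, 1e-9)
  quad <- integrate(function(u) hazard(spec, u), 0, 10, rel.tol = 1e-12)$value
  expect_equal(cumulative_hazard(spec, 0, 10), quad, tolerance = 1e-10)
  expect_equal(cumulative_hazard(spec, 0, 10), 1.0, tolerance = 1e-6)
})

test_that("survival is a proper non-increasing curve for every family", {
  expect_equal(survival_prob(hazard_spec("constant", 0.098), 0), 1.0)
  expect_equal(survival_prob(hazard_spec("constant", 0.098), 24),
               exp(-2.352), tolerance = 1e-12)
  expect_lt(survival_prob(hazard_spec("constant", 1e6), 1), 1e-300)
  set.seed(22)
  t <- seq(0, 48, by = 0.5)
  for (i in 1:10) {
    fam <- sample(c("constant", "gompertz", "weibull"), 1)
    spec <- hazard_spec(fam, runif(1, 0.01, 1), runif(1, -0.4, 0.4))
    s <- survival_prob(spec, t)
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("shape zero reduces Gompertz and Weibull to the constant family", {
  t <- c(0.5, 1, 7, 36)
  s0 <- survival_prob(hazard_spec("constant", 0.13), t)
  expect_equal(survival_prob(hazard_spec("gompertz", 0.13, 0), t), s0)
  expect_equal(survival_prob(hazard_spec("weibull", 0.13, 0), t), s0)
})

test_that("median survival time solves S(t) = 0.5", {
  expect_equal(median_survival_time(hazard_spec("constant", 0.098)),
               log(2) / 0.098)
  expect_equal(median_survival_time(hazard_spec("constant", log(2))), 1.0)
  # identity for the constant family (closed form, no root finding)
  for (b0 in c(0.01, 0.098, 1.3)) {
    expect_equal(median_survival_time(hazard_spec("constant", b0)) * b0,
                 log(2), tolerance = 1e-15)
  }
  # Weibull: numerical root against the closed form ((b1+1) ln2 / b0)^(1/(b1+1))
  spec <- hazard_spec("weibull", 0.05, 0.5)
  closed <- ((0.5 + 1) * log(2) / 0.05)^(1 / 1.5)
  expect_equal(median_survival_time(spec), closed, tolerance = 1e-8)
  expect_equal(survival_prob(spec, median_survival_time(spec)), 0.5,
               tolerance = 1e-7)
})

test_that("covariate model reproduces the published hazard multipliers", {
  cm <- covariate_model(terms = c(age_median = 0.017, ps2_pct = 0.004),
                        refs = c(age_median = 72.5, ps2_pct = 14))
  # identity at the reference values
  expect_equal(apply_covariates(0.098, cm, list(age_median = 72.5, ps2_pct = 14)),
               0.098)
  # age 80 at reference PS2
  expect_equal(apply_covariates(0.098, cm, list(age_median = 80, ps2_pct = 14)),
               0.098 * exp(7.5 * 0.017))
  # +10 years of age multiplies the hazard by e^0.17 = 1.185
  r <- apply_covariates(0.098, cm, list(age_median = 82.5, ps2_pct = 14)) /
    apply_covariates(0.098, cm, list(age_median = 72.5, ps2_pct = 14))
  expect_equal(r, exp(10 * 0.017))
  expect_equal(round(r, 3), 1.185)
  expect_error(apply_covariates(0.098, cm, list(age_median = 80)),
               "ps2_pct")
})

test_that("covariate round trip: multiplier out, multiplier back in", {
  set.seed(33)
  cm <- covariate_model(terms = c(age_median = 0.017, ps2_pct = 0.004),
                        refs = c(age_median = 72.5, ps2_pct = 14))
  for (i in 1:8) {
    vals <- list(age_median = runif(1, 59, 76), ps2_pct = runif(1, 0, 100))
    eta <- rnorm(1, 0, 0.2)
    b <- apply_covariates(0.098, cm, vals, eta)
    m <- covariate_multiplier(cm, vals)
    expect_equal(b / m, 0.098 * exp(eta), tolerance = 1e-15)
  }
})
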