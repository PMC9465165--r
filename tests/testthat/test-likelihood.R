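ref_params <- function(omega2 = 0.146^2, sigma = 0.822, beta0 = 0.1) {
  population_params(spec = hazard_spec("constant", beta0),
                    cov_model = covariate_model(), omega2 = omega2,
                    sigma_eps = sigma)
}

test_that("conditional deviance reduces to its closed forms", {
  arms <- make_arms(1)
  cur <- make_curves(arms, beta0 = 0.1)  # obs = prediction exactly
  p0 <- ref_params(omega2 = 0)
  expect_equal(conditional_neg2ll(p0, 0, arms[1, ], cur),
               sum(log(2 * pi * (cur$se * 0.822)^2)))
  # a single observation one standardized residual away contributes
  # 1 + ln(2*pi*(se*sigma)^2)
  one <- cur[1, ]
  one$survival <- exp(-0.1 * one$time_months) + one$se * 0.822
  expect_equal(conditional_neg2ll(p0, 0, arms[1, ], one),
               1 + log(2 * pi * (one$se * 0.822)^2))
  expect_error(conditional_neg2ll(p0, 0.1, arms[1, ], cur), "degenerate")
})

test_that("conditional deviance matches a direct Gaussian density sum", {
  set.seed(44)
  arms <- make_arms(1, age = 68, ps2 = 30)
  p <- population_params(omega2 = 0.04, sigma_eps = 0.7)
  eta <- 0.15
  cur <- data.frame(arm_id = "A01", time_months = c(2, 5, 9, 14),
                    survival = runif(4, 0.2, 0.9), se = runif(4, 0.01, 0.08))
  # independent oracle: product of normal densities plus the eta prior
  beta_i <- 0.098 * exp((68 - 72.5) * 0.017 + (30 - 14) * 0.004 + eta)
  pred <- exp(-beta_i * cur$time_months)
  oracle <- -2 * (sum(dnorm(cur$survival, pred, cur$se * 0.7, log = TRUE)) +
                  dnorm(eta, 0, 0.2, log = TRUE))
  expect_equal(conditional_neg2ll(p, eta, arms[1, ], cur), oracle,
               tolerance = 1e-10)
})

test_that("Laplace marginal OFV matches adaptive Gauss-Hermite quadrature", {
  for (s in 1:3) {
    g <- generate_survival_dataset(
      generator_config(n_studies = 3, n_arms = 3, regimens = c("GV", "GD", "G")),
      seed = 50 + s)
    p <- truth_params()
    lap <- marginal_ofv(p, g$dataset)
    agq <- marginal_ofv(p, g$dataset, method = "aghq", nodes = 64)
    expect_lt(abs(lap - agq), 0.1)
  }
})

test_that("zero inter-study variance drops the integral and the prior", {
  ds <- make_flat_dataset(3, beta0 = 0.12)
  p0 <- ref_params(omega2 = 0, beta0 = 0.12)
  direct <- sum(vapply(1:3, function(i) {
    cur <- ds$curves[ds$curves$arm_id == ds$arms$arm_id[i], ]
    conditional_neg2ll(p0, 0, ds$arms[i, ], cur)
  }, numeric(1)))
  expect_equal(marginal_ofv(p0, ds), direct, tolerance = 1e-10)
})

test_that("OFV is invariant to arm and row permutations, additive over copies", {
  g <- generate_survival_dataset(
    generator_config(n_studies = 4, n_arms = 4,
                     regimens = c("GV", "GD", "G", "G")), seed = 61)
  p <- truth_params()
  base <- marginal_ofv(p, g$dataset)
  # permute arms and shuffle curve rows
  perm <- mbma_dataset(g$dataset$arms[c(3, 1, 4, 2), ],
                       g$dataset$curves[sample(nrow(g$dataset$curves)), ],
                       monotone = "ignore")
  expect_equal(marginal_ofv(p, perm), base, tolerance = 1e-9)
  # duplicating every arm (fresh ids) doubles the OFV
  arms2 <- g$dataset$arms
  arms2$arm_id <- paste0(arms2$arm_id, "_dup")
  arms2$study_id <- paste0(arms2$study_id, "_dup")
  cur2 <- g$dataset$curves
  cur2$arm_id <- paste0(cur2$arm_id, "_dup")
  doubled <- mbma_dataset(rbind(g$dataset$arms, arms2),
                          rbind(g$dataset$curves, cur2), monotone = "ignore")
  expect_equal(marginal_ofv(p, doubled), 2 * base, tolerance = 1e-9)
})

test_that("adding a covariate with zero coefficient leaves the OFV unchanged", {
  g <- generate_survival_dataset(generator_config(), seed = 62)
  p_plain <- ref_params()
  p_zero <- population_params(
    spec = hazard_spec("constant", 0.1),
    cov_model = covariate_model(c(age_median = 0), c(age_median = 72.5)),
    omega2 = 0.146^2, sigma_eps = 0.822)
  expect_equal(marginal_ofv(p_zero, g$dataset),
               marginal_ofv(p_plain, g$dataset), tolerance = 1e-12)
})

test_that("empirical-Bayes eta recovers, shrinks and flips sign", {
  arms <- make_arms(1)
  p <- ref_params()
  # data generated at eta = 0.2 with tight SEs
  cur <- make_curves(arms, beta0 = 0.1, se = 0.002, eta = 0.2)
  eb <- empirical_bayes_eta(p, arms[1, ], cur)
  expect_equal(eb$eta_hat, 0.2, tolerance = 0.02)
  expect_gt(eb$curvature, 0)
  # strong shrinkage as omega2 -> 0 (mode pulled from 0.2 towards 0)
  p_tiny <- ref_params(omega2 = 1e-8)
  expect_lt(abs(empirical_bayes_eta(p_tiny, arms[1, ], cur)$eta_hat), 0.01)
  expect_identical(empirical_bayes_eta(ref_params(omega2 = 0), arms[1, ],
                                       cur)$eta_hat, 0)
  # reflecting observations around the eta = 0 prediction flips the sign
  pred0 <- exp(-0.1 * cur$time_months)
  refl <- cur
  refl$survival <- pmin(pmax(2 * pred0 - cur$survival, 0), 1)
  eb_r <- empirical_bayes_eta(p, arms[1, ], refl)
  expect_lt(eb_r$eta_hat, 0)
})
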