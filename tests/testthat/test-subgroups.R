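# minimal fitted-model stand-in with a chosen covariance, for simulation tests
fake_fit <- function(beta0 = 0.098, thetas = c(age_median = 0.017, ps2_pct = 0.004),
                     refs = c(age_median = 72.5, ps2_pct = 14),
                     covariance = NULL) {
  pn <- c("log_beta0", paste0("theta_", names(thetas)))
  par <- c(log(beta0), unname(thetas))
  names(par) <- pn
  if (!is.null(covariance)) dimnames(covariance) <- list(pn, pn)
  structure(list(par = par, par_names = pn, covariance = covariance,
                 term_names = names(thetas), refs = refs,
                 family = "constant",
                 params = population_params(
                   spec = hazard_spec("constant", beta0),
                   cov_model = covariate_model(thetas, refs),
                   omega2 = 0.146^2, sigma_eps = 0.822),
                 converged = TRUE),
            class = "mbma_fit")
}

test_that("covariate correction inverts the covariate multiplier exactly", {
  g <- generate_survival_dataset(generator_config(), seed = 111)
  f <- fit_model(g$dataset, covariate_terms = c("age_median", "ps2_pct"),
                 cov_refs = c(age_median = 72.5, ps2_pct = 14))
  corr <- covariate_correct(f, g$dataset)
  expect_equal(nrow(corr), 20)
  # round trip: corrected beta times the multiplier restores the individual beta
  expect_equal(corr$beta_corrected * corr$multiplier, corr$beta_individual,
               tolerance = 1e-14)
  expect_equal(corr$beta_corrected,
               f$params$spec$beta0 * exp(corr$eta_hat), tolerance = 1e-14)
  expect_true(all(is.finite(corr$se_log) & corr$se_log > 0))
})

test_that("an arm at the reference covariates needs no correction", {
  ds <- make_flat_dataset(3, beta0 = 0.1)  # covariates at the references
  # noise-free identical arms make the covariate Hessian singular; the
  # covariance warning is expected and irrelevant here
  f <- suppressWarnings(
    fit_model(ds, covariate_terms = c("age_median", "ps2_pct"),
              cov_refs = c(age_median = 72.5, ps2_pct = 14),
              omega2 = 0.01, sigma_eps = 1))
  corr <- covariate_correct(f, ds)
  expect_equal(corr$multiplier, rep(1, 3))
  expect_equal(corr$beta_corrected, corr$beta_individual)
})

test_that("regimen pooling matches hand-coded DerSimonian-Laird arithmetic", {
  corr <- data.frame(arm_id = c("a", "b", "c"), regimen = "G", n = 50,
                     eta_hat = 0, multiplier = 1,
                     beta_individual = exp(c(-2.3, -2.2, -2.4)),
                     beta_corrected = exp(c(-2.3, -2.2, -2.4)),
                     se_log = 0.05)
  pooled <- pool_regimen(corr, "G")
  oracle <- dl_oracle(c(-2.3, -2.2, -2.4), rep(0.05^2, 3))
  expect_equal(pooled$log_beta, oracle$est, tolerance = 1e-10)
  expect_equal(pooled$se, oracle$se, tolerance = 1e-10)
  expect_equal(pooled$tau2, oracle$tau2, tolerance = 1e-10)
  # identical arms pool to themselves with no heterogeneity
  corr2 <- corr
  corr2$beta_corrected <- rep(0.1, 3)
  p2 <- pool_regimen(corr2, "G")
  expect_equal(p2$beta, 0.1, tolerance = 1e-12)
  expect_equal(p2$tau2, 0)
  # single-arm pass-through
  expect_equal(pool_regimen(corr[1, ], "G")$log_beta, -2.3)
})

test_that("zero-uncertainty simulation collapses to the analytic curve", {
  p <- population_params()  # published point estimates, no covariance
  s <- simulate_typical_os(p, scenario = list(age_median = 80, ps2_pct = 14),
                           n_draws = 500, seed = 2)
  h <- 0.098 * exp(7.5 * 0.017)
  expect_equal(s$mst, log(2) / h, tolerance = 1e-12)
  expect_equal(s$mst_lo, s$mst_hi)          # interval collapses
  expect_equal(s$surv24, 100 * exp(-24 * h), tolerance = 1e-12)
})

test_that("simulation intervals widen with parameter variance", {
  base_cov <- diag(c(0.062^2, (0.017 * 0.356)^2, (0.004 * 0.354)^2))
  widths <- vapply(c(1, 4, 16), function(k) {
    f <- fake_fit(covariance = base_cov * k)
    s <- simulate_typical_os(f, scenario = list(age_median = 70, ps2_pct = 14),
                             n_draws = 2000, seed = 3)
    s$mst_hi - s$mst_lo
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("the subgroup table orders scenarios by risk", {
  f <- fake_fit(covariance = diag(c(0.062^2, (0.017 * 0.356)^2,
                                    (0.004 * 0.354)^2)))
  tab <- subgroup_table(f, n_draws = 2000, seed = 4)
  expect_equal(tab$label, c("age_60", "age_70", "age_80", "ps0_1", "ps2"))
  expect_true(all(diff(tab$mst[1:3]) < 0))      # older, shorter survival
  expect_gt(tab$mst[4], tab$mst[5])             # PS2 worse than PS0-1
  # survival percentages decrease with horizon in every scenario
  expect_true(all(tab$surv12 > tab$surv24 & tab$surv24 > tab$surv36))
  expect_true(all(tab$mst_lo <= tab$mst & tab$mst <= tab$mst_hi))
})

test_that("regimen pooling yields overlapping intervals under a common hazard", {
  g <- generate_survival_dataset(generator_config(), seed = 112)
  f <- fit_model(g$dataset, covariate_terms = c("age_median", "ps2_pct"),
                 cov_refs = c(age_median = 72.5, ps2_pct = 14))
  tab <- regimen_table(f, g$dataset, n_draws = 2000, seed = 5)
  expect_equal(sort(tab$label), c("G", "GD", "GV"))
  expect_equal(tab$k[order(tab$label)], c(8, 6, 6))
  # all regimens share one generating hazard: the three intervals overlap
  expect_lt(max(tab$mst_lo), min(tab$mst_hi))
})
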