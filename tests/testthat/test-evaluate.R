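test_that("VPC bands collapse onto the typical curve without variability", {
  ds <- make_flat_dataset(2, beta0 = 0.1)
  p <- population_params(spec = hazard_spec("constant", 0.1),
                         cov_model = covariate_model(), omega2 = 0,
                         sigma_eps = 1e-6)
  vpc <- visual_predictive_check(p, ds, n_sim = 200, seed = 5)
  pred <- exp(-0.1 * vpc$table$time_months)
  expect_equal(vpc$table$predicted_median, pred, tolerance = 1e-5)
  expect_lt(max(vpc$table$band_upper - vpc$table$band_lower), 1e-4)
  expect_warning(visual_predictive_check(p, ds, n_sim = 50, seed = 5),
                 "unstable")
})

test_that("VPC median band is monotone for the constant-hazard model", {
  g <- generate_survival_dataset(generator_config(), seed = 101)
  vpc <- visual_predictive_check(truth_params(), g$dataset, n_sim = 300,
                                 seed = 6)
  for (id in unique(vpc$table$arm_id)) {
    d <- vpc$table[vpc$table$arm_id == id, ]
    d <- d[order(d$time_months), ]
    expect_true(all(diff(d$predicted_median) <= 1e-3))
    expect_true(all(d$band_lower <= d$predicted_median + 1e-12))
    expect_true(all(d$predicted_median <= d$band_upper + 1e-12))
  }
  expect_true(vpc$coverage >= 0 && vpc$coverage <= 1)
})

test_that("goodness-of-fit has one row per point and zero residuals on a perfect fit", {
  ds <- make_flat_dataset(2, beta0 = 0.1)
  f <- fit_model(ds, omega2 = 0, sigma_eps = 1)
  gof <- goodness_of_fit(f, ds)
  expect_equal(nrow(gof), nrow(ds$curves))
  expect_lt(max(abs(gof$weighted_residual)), 1e-3)
  expect_equal(gof$pred_population, gof$pred_individual, tolerance = 1e-8)
})

test_that("weighted residuals from a well-specified model look Gaussian", {
  g <- generate_survival_dataset(generator_config(), seed = 102)
  f <- fit_model(g$dataset, covariate_terms = c("age_median", "ps2_pct"),
                 cov_refs = c(age_median = 72.5, ps2_pct = 14))
  gof <- goodness_of_fit(f, g$dataset)
  expect_gt(shapiro.test(gof$weighted_residual)$p.value, 0.01)
  # individual predictions use the EB eta, population predictions eta = 0
  expect_false(isTRUE(all.equal(gof$pred_population, gof$pred_individual)))
})

test_that("leave-one-out needs three units and respects duplicate symmetry", {
  expect_error(leave_one_out(make_flat_dataset(2), family = "constant"),
               "at least 3")
  # four studies, two of them identical: the folds dropping the duplicates
  # must give identical estimates
  arms <- make_arms(4)
  arms$age_median <- c(65, 65, 70, 75)
  cur <- make_curves(arms, beta0 = 0.1, eta = c(0.1, 0.1, -0.05, 0))
  ds <- mbma_dataset(arms, cur)
  loo <- leave_one_out(ds, family = "constant", omega2 = 0.02, sigma_eps = 1)
  expect_equal(nrow(loo$folds), 4)
  expect_true(all(loo$folds$converged))
  f1 <- loo$folds[loo$folds$held_out == "S01", "beta0"]
  f2 <- loo$folds[loo$folds$held_out == "S02", "beta0"]
  expect_equal(f1, f2, tolerance = 1e-5)
  expect_true(all(c("min", "median", "max") %in% names(loo$summary)))
})

test_that("leave-one-out estimates are stable on homogeneous data", {
  g <- generate_survival_dataset(
    generator_config(n_studies = 6, n_arms = 6,
                     regimens = rep(c("GV", "GD", "G"), 2)), seed = 103)
  loo <- leave_one_out(g$dataset, family = "constant")
  b <- loo$summary[loo$summary$parameter == "beta0", ]
  expect_lt((b$max - b$min) / b$median, 0.35)
})
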