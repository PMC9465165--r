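test_that("homogeneous arms pool to their common proportion", {
  p <- pool_proportions(c(20, 20, 20), c(100, 100, 100))
  expect_equal(p$pooled_pct, 20, tolerance = 1e-10)
  expect_equal(p$tau2, 0)
  expect_equal(p$k, 3)
  expect_equal(p$n_total, 300)
  expect_true(p$ci_lower < 20 && 20 < p$ci_upper)
})

test_that("fixed-effect raw pooling matches hand-coded inverse-variance arithmetic", {
  ev <- c(10, 30); n <- c(100, 100)
  p <- pool_proportions(ev, n, transform = "raw", method = "FE")
  pi <- ev / n
  vi <- pi * (1 - pi) / n
  oracle <- sum(pi / vi) / sum(1 / vi)
  expect_equal(p$pooled_pct, 100 * oracle, tolerance = 1e-10)
})

test_that("DL pooling on the logit scale matches the textbook oracle", {
  ev <- c(12, 30, 9); n <- c(60, 120, 45)
  p <- pool_proportions(ev, n, transform = "logit", method = "DL")
  yi <- log(ev / (n - ev))
  vi <- 1 / ev + 1 / (n - ev)
  oracle <- dl_oracle(yi, vi)
  expect_equal(p$pooled_pct, 100 * plogis(oracle$est), tolerance = 1e-10)
  expect_equal(p$tau2, oracle$tau2, tolerance = 1e-10)
  expect_equal(p$ci_lower, 100 * plogis(oracle$est - 1.96 * oracle$se),
               tolerance = 1e-10)
})

test_that("boundary proportions get a continuity correction with a warning", {
  expect_warning(p <- pool_proportions(c(0, 5), c(40, 50)), "continuity")
  expect_true(is.finite(p$pooled_pct))
  expect_true(p$ci_lower >= 0 && p$ci_upper <= 100)
})

test_that("the pooled estimate stays within the span of the arm proportions", {
  set.seed(55)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    n <- sample(30:200, k, replace = TRUE)
    ev <- rbinom(k, n, runif(1, 0.05, 0.6))
    ev <- pmin(pmax(ev, 1), n - 1)
    p <- pool_proportions(ev, n)
    props <- 100 * ev / n
    expect_gte(p$pooled_pct, min(props) - 1e-8)
    expect_lte(p$pooled_pct, max(props) + 1e-8)
  }
})

test_that("the endpoint report is a full endpoint-by-regimen grid", {
  g <- generate_survival_dataset(generator_config(), seed = 121)
  cnt <- generate_count_data(g$dataset$arms, seed = 122)
  ds <- mbma_dataset(g$dataset$arms, g$dataset$curves, cnt, monotone = "ignore")
  rep <- suppressWarnings(endpoint_report(ds))  # boundary counts warn
  expect_equal(nrow(rep), 7 * 3)
  expect_true(all(rep$k > 0))
  expect_true(all(rep$pooled_pct >= 0 & rep$pooled_pct <= 100))
  # dropping one regimen leaves a 7 x 2 grid with absences flagged as absent
  keep <- g$dataset$arms$regimen != "GD"
  arms2 <- g$dataset$arms[keep, ]
  cur2 <- g$dataset$curves[g$dataset$curves$arm_id %in% arms2$arm_id, ]
  cnt2 <- cnt[cnt$arm_id %in% arms2$arm_id, ]
  rep2 <- suppressWarnings(
    endpoint_report(mbma_dataset(arms2, cur2, cnt2, monotone = "ignore")))
  expect_equal(nrow(rep2), 7 * 2)
  expect_false("GD" %in% rep2$regimen)
})

test_that("a homogeneous count fixture reproduces its generating proportions", {
  arms <- make_arms(3, regimen = "G", n = 400)
  cnt <- data.frame(arm_id = arms$arm_id, endpoint = "ORR",
                    events = c(55, 56, 55), total = 400)
  ds <- mbma_dataset(arms, make_curves(arms), cnt)
  rep <- endpoint_report(ds)
  g_orr <- rep[rep$endpoint == "ORR" & rep$regimen == "G", ]
  expect_equal(g_orr$pooled_pct, 100 * mean(c(55, 56, 55) / 400),
               tolerance = 0.05)
})
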