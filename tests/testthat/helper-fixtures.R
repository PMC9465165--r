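# Fixtures are built in code; nothing is read from disk.

# minimal arms table with k arms (covariates at the reference values unless
# overridden), one study per arm
make_arms <- function(k = 2, regimen = "G", age = 72.5, ps2 = 14, n = 100) {
  data.frame(
    study_id = sprintf("S%02d", seq_len(k)),
    arm_id = sprintf("A%02d", seq_len(k)),
    regimen = rep_len(regimen, k), n = rep_len(n, k),
    age_median = rep_len(age, k), male_pct = 80, ps2_pct = rep_len(ps2, k),
    stage4_pct = 79, scc_pct = 34, adc_pct = 41.1, lcc_pct = 9.8,
    stringsAsFactors = FALSE)
}

# noiseless curves under a constant hazard per arm
make_curves <- function(arms, beta0 = 0.1, times = 1:24, se = 0.02,
                        eta = rep(0, nrow(arms))) {
  do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    s <- exp(-beta0 * exp(eta[i]) * times)
    data.frame(arm_id = arms$arm_id[i], time_months = times, survival = s,
               se = se, stringsAsFactors = FALSE)
  }))
}

make_flat_dataset <- function(k = 2, beta0 = 0.1, times = 1:24, se = 0.02,
                              eta = rep(0, k), ...) {
  arms <- make_arms(k, ...)
  mbma_dataset(arms, make_curves(arms, beta0, times, se, eta))
}

# paper-scale generating truth
truth_params <- function() population_params()

# hand-coded DerSimonian-Laird pooling, textbook arithmetic -- the
# independent oracle for all DL-based routines
dl_oracle <- function(yi, vi) {
  wi <- 1 / vi
  ybar <- sum(wi * yi) / sum(wi)
  Q <- sum(wi * (yi - ybar)^2)
  df <- length(yi) - 1
  C <- sum(wi) - sum(wi^2) / sum(wi)
  tau2 <- max(0, (Q - df) / C)
  wi_star <- 1 / (vi + tau2)
  est <- sum(wi_star * yi) / sum(wi_star)
  se <- sqrt(1 / sum(wi_star))
  list(est = est, se = se, tau2 = tau2)
}
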