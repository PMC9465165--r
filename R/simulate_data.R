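# Covariate sampling ranges per regimen stratum, matching the min-max spread
# of the baseline table of the 17-study / 20-arm literature dataset the
# analysis emulates. Age (and PS2) differ systematically between the
# doublet regimens and single-agent gemcitabine, which is exactly the
# covariate-regimen confounding the model-based analysis is built to remove.
REGIMEN_RANGES <- list(
  GV = list(n = c(20, 215), age = c(59.0, 65.0), male = c(59, 86),
            ps2 = c(2, 26), stage4 = c(67, 93), scc = c(21, 40),
            adc = c(46, 55), lcc = c(4, 10.5)),
  GD = list(n = c(19, 144), age = c(61.4, 76.0), male = c(66, 90),
            ps2 = c(0, 19.6), stage4 = c(65, 100), scc = c(12, 38),
            adc = c(30.4, 58), lcc = c(7.1, 16)),
  G  = list(n = c(28, 122), age = c(72.0, 76.0), male = c(57, 86.9),
            ps2 = c(20.5, 100), stage4 = c(61.9, 96), scc = c(18, 50),
            adc = c(27.4, 57), lcc = c(4.9, 15.4))
)

# Overall admissible ranges (pooled min-max across regimens).
OVERALL_RANGES <- list(n = c(19, 215), age = c(59.0, 76.0), ps2 = c(0, 100))

#' Configuration of the synthetic survival-data generator
#'
#' Defines the study conditions the generator reproduces: 17 studies
#' contributing 20 treatment arms (6 GV, 6 GD, 8 G), per-arm sample sizes in
#' 19-215 patients, covariates sampled uniformly within each regimen's
#' baseline min-max range, monthly survival observations up to a per-arm
#' follow-up horizon sampled in 12-36 months, and the generating population
#' parameters (defaults: constant hazard 0.098/month, age coefficient 0.017
#' centred at 72.5 years, PS2 coefficient 0.004 centred at 14%, inter-study
#' SD 0.146 on the log-hazard scale, residual scale 0.822).
#'
#' @param n_studies number of studies.
#' @param n_arms total number of treatment arms (>= n_studies; the first
#'   `n_arms - n_studies` studies contribute two arms each).
#' @param regimens regimen allocation over arms.
#' @param params a [population_params()] holding the generating truth.
#' @param grid_step observation spacing in months.
#' @param horizon_range per-arm follow-up horizon range in months.
#' @param se_floor floor on binomial standard errors.
#' @param n_scale multiplier on sampled per-arm sample sizes (power studies
#'   use values > 1; the baseline conditions use 1).
#' @param confounded if `TRUE` (default) covariates are sampled within each
#'   regimen's own range, reproducing the age/PS-regimen confounding of the
#'   real literature; if `FALSE` all arms draw from the pooled ranges, which
#'   separates covariate effects from regimen effects in tests.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_studies = 17, n_arms = 20,
                             regimens = rep(c("GV", "GD", "G"), c(6, 6, 8)),
                             params = population_params(),
                             grid_step = 1, horizon_range = c(12, 36),
                             se_floor = 0.005, confounded = TRUE,
                             n_scale = 1) {
  stopifnot(n_arms >= n_studies, length(regimens) == n_arms,
            all(regimens %in% REGIMENS), grid_step > 0, n_scale > 0,
            length(horizon_range) == 2, horizon_range[1] <= horizon_range[2])
  structure(list(n_studies = n_studies, n_arms = n_arms, regimens = regimens,
                 params = params, grid_step = grid_step,
                 horizon_range = horizon_range, se_floor = se_floor,
                 confounded = confounded, n_scale = n_scale),
            class = "generator_config")
}

#' Population parameters of the survival meta-model
#'
#' Bundles the typical baseline hazard (as a [hazard_spec()]), the covariate
#' model, the inter-study variance \eqn{\omega^2} of the log-scale random
#' effect \eqn{\eta}, and the residual scale \eqn{\sigma_\epsilon}
#' multiplying each observation's standard error.
#'
#' @param spec a [hazard_spec()]; its `beta0` is the typical baseline hazard.
#' @param cov_model a [covariate_model()].
#' @param omega2 inter-study variance (>= 0) on the log-hazard scale.
#' @param sigma_eps residual scale; must be positive for likelihood work,
#'   but 0 is accepted as the noiseless generation limit.
#' @return an object of class `population_params`.
#' @export
population_params <- function(spec = hazard_spec("constant", 0.098),
                              cov_model = covariate_model(
                                terms = c(age_median = 0.017, ps2_pct = 0.004),
                                refs = c(age_median = 72.5, ps2_pct = 14)),
                              omega2 = 0.146^2, sigma_eps = 0.822) {
  stopifnot(inherits(spec, "hazard_spec"), inherits(cov_model, "covariate_model"),
            omega2 >= 0, sigma_eps >= 0)
  structure(list(spec = spec, cov_model = cov_model, omega2 = omega2,
                 sigma_eps = sigma_eps),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("<population_params> family=%s beta_typical=%g omega2=%g sigma_eps=%g\n",
              x$spec$family, x$spec$beta0, x$omega2, x$sigma_eps))
  print(x$cov_model)
  invisible(x)
}

runif1 <- function(rng) stats::runif(1, rng[1], rng[2])

#' Generate a synthetic study-level survival dataset
#'
#' Runs the assumed data-generating model forward: for each arm, covariates
#' and sample size are sampled within the regimen's baseline ranges, a
#' log-scale inter-study effect \eqn{\eta \sim N(0, \omega^2)} is drawn, the
#' individual hazard follows from the covariate model, the survival curve is
#' evaluated on the observation grid, binomial standard errors are attached,
#' and observed survival is the prediction plus \eqn{SE \cdot \sigma_\epsilon}
#' times standard-normal noise. Observations are clipped to \[0, 1\] only at
#' emission; the truth record keeps the pre-clip values so likelihood checks
#' remain exact.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (mandatory; the output is deterministic given it).
#' @return a list with elements `dataset` (an `mbma_dataset`, SEs resolved)
#'   and `truth` (generating parameters, per-arm eta and covariates, and the
#'   unclipped observations).
#' @export
generate_survival_dataset <- function(config = generator_config(), seed) {
  stopifnot(inherits(config, "generator_config"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  p <- config$params
  n_two_arm <- config$n_arms - config$n_studies

  study_of_arm <- character(config$n_arms)
  k <- 1L
  for (s in seq_len(config$n_studies)) {
    arms_here <- if (s <= n_two_arm) 2L else 1L
    for (a in seq_len(arms_here)) {
      study_of_arm[k] <- sprintf("S%02d", s)
      k <- k + 1L
    }
  }

  arms <- vector("list", config$n_arms)
  curves <- vector("list", config$n_arms)
  eta <- numeric(config$n_arms)
  unclipped <- vector("list", config$n_arms)
  for (i in seq_len(config$n_arms)) {
    reg <- config$regimens[i]
    rr <- if (config$confounded) REGIMEN_RANGES[[reg]] else {
      list(n = OVERALL_RANGES$n, age = OVERALL_RANGES$age, male = c(57, 90),
           ps2 = OVERALL_RANGES$ps2, stage4 = c(61.9, 100), scc = c(12, 50),
           adc = c(27.4, 58), lcc = c(4, 21))
    }
    arm_id <- sprintf("%s_arm%02d", study_of_arm[i], i)
    arm <- data.frame(
      study_id = study_of_arm[i], arm_id = arm_id, regimen = reg,
      n = round(runif1(rr$n) * config$n_scale), age_median = round(runif1(rr$age), 1),
      male_pct = round(runif1(rr$male), 1), ps2_pct = round(runif1(rr$ps2), 1),
      stage4_pct = round(runif1(rr$stage4), 1), scc_pct = round(runif1(rr$scc), 1),
      adc_pct = round(runif1(rr$adc), 1), lcc_pct = round(runif1(rr$lcc), 1),
      stringsAsFactors = FALSE)
    eta[i] <- stats::rnorm(1, 0, sqrt(p$omega2))
    beta_i <- apply_covariates(p$spec$beta0, p$cov_model, arm, eta[i])
    spec_i <- hazard_spec(p$spec$family, beta_i, p$spec$beta1)
    horizon <- runif1(config$horizon_range)
    times <- seq(config$grid_step, horizon, by = config$grid_step)
    s_true <- survival_prob(spec_i, times)
    se <- pmax(sqrt(s_true * (1 - s_true) / arm$n), config$se_floor)
    obs_raw <- s_true + se * p$sigma_eps * stats::rnorm(length(times))
    curves[[i]] <- data.frame(arm_id = arm_id, time_months = times,
                              survival = pmin(pmax(obs_raw, 0), 1), se = se,
                              stringsAsFactors = FALSE)
    unclipped[[i]] <- obs_raw
    arms[[i]] <- arm
  }
  arms <- do.call(rbind, arms)
  # additive residual noise legitimately breaks monotonicity; do not repair
  dataset <- mbma_dataset(arms, do.call(rbind, curves), monotone = "ignore")
  truth <- list(params = p,
                eta = stats::setNames(eta, arms$arm_id),
                covariates = arms,
                unclipped = stats::setNames(unclipped, arms$arm_id),
                seed = seed)
  list(dataset = dataset, truth = truth)
}

#' Generate synthetic response/toxicity count data
#'
#' For each arm and endpoint, the arm-level event probability is drawn
#' logit-normally around the endpoint's true proportion for that regimen
#' (between-arm heterogeneity on the logit scale), and the event count is a
#' binomial draw with the arm's sample size.
#'
#' @param arms data.frame of arms (needs arm_id, regimen, n).
#' @param true_props data.frame with columns endpoint, regimen, p (true
#'   proportions, strictly inside (0, 1)).
#' @param het_sd between-arm SD on the logit scale.
#' @param seed integer seed.
#' @return counts data.frame (arm_id, endpoint, events, total).
#' @export
generate_count_data <- function(arms, true_props = default_true_props(),
                                het_sd = 0.2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(c("endpoint", "regimen", "p") %in% names(true_props)))
  if (any(true_props$p <= 0 | true_props$p >= 1)) {
    stop("true proportions must be strictly inside (0, 1)")
  }
  set.seed(seed)
  out <- list()
  for (j in seq_len(nrow(true_props))) {
    ep <- true_props$endpoint[j]; reg <- true_props$regimen[j]
    sel <- arms[arms$regimen == reg, , drop = FALSE]
    if (!nrow(sel)) next
    lp <- stats::qlogis(true_props$p[j]) + stats::rnorm(nrow(sel), 0, het_sd)
    pr <- stats::plogis(lp)
    out[[length(out) + 1L]] <- data.frame(
      arm_id = sel$arm_id, endpoint = ep,
      events = stats::rbinom(nrow(sel), sel$n, pr), total = sel$n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Default generating proportions for response and grade 3-4 toxicity
#'
#' Pooled point estimates by regimen used as generating truths for the count
#' simulator (fractions, not percentages).
#'
#' @return data.frame with columns endpoint, regimen, p.
#' @export
default_true_props <- function() {
  grid <- expand.grid(endpoint = ENDPOINTS, regimen = REGIMENS,
                      stringsAsFactors = FALSE)
  vals <- c(
    ORR = NA, anemia = NA, leukopenia = NA, neutropenia = NA,
    thrombocytopenia = NA, nausea_vomiting = NA, fatigue_asthenia = NA)
  tab <- rbind(
    GV = c(0.284, 0.021, 0.083, 0.209, 0.030, 0.027, 0.067),
    GD = c(0.285, 0.051, 0.150, 0.164, 0.046, 0.026, 0.093),
    G  = c(0.138, 0.047, 0.116, 0.187, 0.034, 0.036, 0.033))
  colnames(tab) <- ENDPOINTS
  grid$p <- tab[cbind(grid$regimen, grid$endpoint)]
  grid
}
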