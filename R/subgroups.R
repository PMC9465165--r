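#' Covariate-corrected per-arm baseline hazards
#'
#' Inverts the covariate model for each arm: the arm's individual baseline
#' hazard \eqn{\beta_i = \beta_{typical} m_i e^{\hat\eta_i}} (with
#' \eqn{m_i} the covariate multiplier) is divided by \eqn{m_i}, leaving
#' \eqn{\beta_{corrected} = \beta_{typical} e^{\hat\eta_i}} — all arms placed
#' at the reference covariate values, so remaining differences reflect the
#' regimen and the study effect, not the covariate mix. The log-scale
#' standard error of each corrected value comes from the curvature of the
#' Bayesian-feedback objective (`sqrt(2 / curvature)`).
#'
#' @param fit an `mbma_fit` of the final covariate model.
#' @param dataset the fitted dataset.
#' @return data.frame (arm_id, regimen, n, eta_hat, multiplier,
#'   beta_individual, beta_corrected, se_log).
#' @export
covariate_correct <- function(fit, dataset) {
  stopifnot(inherits(fit, "mbma_fit"))
  arms <- dataset$arms
  out <- data.frame(arm_id = arms$arm_id, regimen = arms$regimen, n = arms$n,
                    eta_hat = NA_real_, multiplier = NA_real_,
                    beta_individual = NA_real_, beta_corrected = NA_real_,
                    se_log = NA_real_, row.names = NULL)
  for (i in seq_len(nrow(arms))) {
    id <- as.character(arms$arm_id[i])
    eta <- fit$eta_hat[[id]]
    m <- covariate_multiplier(fit$params$cov_model, arms[i, ])
    out$eta_hat[i] <- eta
    out$multiplier[i] <- m
    out$beta_individual[i] <- fit$params$spec$beta0 * m * exp(eta)
    out$beta_corrected[i] <- fit$params$spec$beta0 * exp(eta)
    curv <- fit$eta_curvature[[id]]
    out$se_log[i] <- if (is.finite(curv) && curv > 0) sqrt(2 / curv) else NA_real_
  }
  out
}

#' Random-effects pooling of corrected hazards within a regimen
#'
#' DerSimonian-Laird random-effects pooling of the log corrected baseline
#' hazards of one regimen's arms, weighting by the inverse of the
#' Bayesian-feedback variances. A single-arm regimen passes through with its
#' own standard error.
#'
#' @param corrected output of [covariate_correct()].
#' @param regimen regimen code to pool.
#' @return list (regimen, k, log_beta, se, ci_lower, ci_upper, tau2, beta)
#'   on the log scale; `beta` is the back-transformed pooled hazard.
#' @export
pool_regimen <- function(corrected, regimen) {
  sel <- corrected[corrected$regimen == regimen, , drop = FALSE]
  if (!nrow(sel)) stop("no arms with regimen '", regimen, "'")
  yi <- log(sel$beta_corrected)
  vi <- sel$se_log^2
  if (nrow(sel) == 1L) {
    est <- yi; se <- sel$se_log; tau2 <- 0
  } else {
    rm <- metafor::rma(yi = yi, vi = vi, method = "DL")
    est <- as.numeric(rm$beta); se <- rm$se; tau2 <- rm$tau2
  }
  list(regimen = regimen, k = nrow(sel), log_beta = est, se = se,
       ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
       tau2 = tau2, beta = exp(est))
}

# draws of the scenario log baseline hazard (and shape) on the estimation
# scale; returns list(log_beta (n_draws), beta1 (n_draws))
draw_loghazard <- function(object, scenario = NULL, n_draws, seed,
                           include_omega = FALSE) {
  set.seed(seed)
  if (inherits(object, "mbma_fit")) {
    fit <- object
    mu <- fit$par
    keep <- setdiff(fit$par_names, c("log_omega", "log_sigma"))
    mu <- mu[keep]
    if (!is.null(fit$covariance)) {
      Sig <- fit$covariance[keep, keep, drop = FALSE]
      L <- tryCatch(chol(Sig), error = function(e) NULL)
      draws <- if (is.null(L)) {
        matrix(mu, n_draws, length(mu), byrow = TRUE,
               dimnames = list(NULL, keep))
      } else {
        z <- matrix(stats::rnorm(n_draws * length(mu)), n_draws)
        sweep(z %*% L, 2, mu, `+`)
      }
      if (is.null(L)) warning("covariance not positive-definite; ",
                              "simulating at the point estimate (no CI)")
    } else {
      draws <- matrix(mu, n_draws, length(mu), byrow = TRUE,
                      dimnames = list(NULL, keep))
    }
    colnames(draws) <- keep
    lb <- draws[, "log_beta0"]
    tn <- fit$term_names
    if (length(tn)) {
      if (is.null(scenario)) stop("scenario covariate values required")
      miss <- setdiff(tn, names(scenario))
      if (length(miss)) stop("scenario is missing covariate(s): ",
                             paste(miss, collapse = ", "))
      for (nm in tn) {
        lb <- lb + draws[, paste0("theta_", nm)] *
          (as.numeric(scenario[[nm]]) - fit$refs[[nm]])
      }
    }
    if (include_omega && fit$params$omega2 > 0) {
      lb <- lb + stats::rnorm(n_draws, 0, sqrt(fit$params$omega2))
    }
    b1 <- if ("beta1" %in% keep) draws[, "beta1"] else rep(0, n_draws)
    list(log_beta = lb, beta1 = b1, family = fit$family)
  } else if (is.list(object) && !is.null(object$log_beta) &&
             !is.null(object$se)) {
    # pooled regimen hazard
    lb <- stats::rnorm(n_draws, object$log_beta, object$se)
    list(log_beta = lb, beta1 = rep(0, n_draws), family = "constant")
  } else if (inherits(object, "population_params")) {
    if (is.null(scenario)) scenario <- as.list(object$cov_model$refs)
    m <- covariate_multiplier(object$cov_model, scenario)
    lb <- rep(log(object$spec$beta0 * m), n_draws)
    list(log_beta = lb, beta1 = rep(object$spec$beta1, n_draws),
         family = object$spec$family)
  } else {
    stop("unsupported object for simulation")
  }
}

#' Monte Carlo simulation of typical overall survival
#'
#' Draws parameter vectors from a multivariate normal on the estimation scale
#' (log baseline hazard, covariate coefficients, shape) with the estimated
#' covariance, evaluates each draw's survival curve at the scenario covariate
#' values, and summarises median survival time and survival percentages at
#' the requested horizons by the median and 2.5/97.5 percentiles across
#' draws. With zero parameter uncertainty (a `population_params` object, or
#' a fit without covariance) every draw coincides and the summary collapses
#' to the analytic curve.
#'
#' @param object an `mbma_fit`, a pooled-regimen list from [pool_regimen()],
#'   or a [population_params()] (zero uncertainty).
#' @param scenario named covariate values for the scenario (required when the
#'   model has covariate terms).
#' @param n_draws number of Monte Carlo draws (default 10000).
#' @param seed integer seed.
#' @param horizons months at which survival percentages are reported.
#' @param include_omega also draw the inter-study effect (default FALSE:
#'   parameter uncertainty only).
#' @param label scenario label carried into the output.
#' @return one-row data.frame of class `survival_summary`: `mst`, `mst_lo`,
#'   `mst_hi` (months) and `surv<h>`, `surv<h>_lo`, `surv<h>_hi`
#'   (percentages) per horizon.
#' @export
simulate_typical_os <- function(object, scenario = NULL, n_draws = 10000,
                                seed = 1, horizons = c(12, 24, 36),
                                include_omega = FALSE, label = "scenario") {
  d <- draw_loghazard(object, scenario, n_draws, seed, include_omega)
  beta <- exp(d$log_beta)
  if (d$family == "constant") {
    mst <- log(2) / beta
  } else {
    mst <- vapply(seq_along(beta), function(i) {
      median_survival_time(hazard_spec(d$family, beta[i], d$beta1[i]))
    }, numeric(1))
  }
  q3 <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  out <- data.frame(label = label, n_draws = n_draws)
  qq <- q3(mst)
  out$mst <- qq[1]; out$mst_lo <- qq[2]; out$mst_hi <- qq[3]
  for (h in horizons) {
    s <- 100 * exp(-beta * vapply(seq_along(beta), function(i) {
      lambda0_fun(d$family, d$beta1[i], h)
    }, numeric(1)))
    qq <- q3(s)
    out[[paste0("surv", h)]] <- qq[1]
    out[[paste0("surv", h, "_lo")]] <- qq[2]
    out[[paste0("surv", h, "_hi")]] <- qq[3]
  }
  class(out) <- c("survival_summary", "data.frame")
  out
}

#' Subgroup survival table over covariate scenarios
#'
#' One [simulate_typical_os()] summary per scenario. The default scenarios
#' vary median age over 60/70/80 years with the PS2 proportion at its
#' reference value, and the PS2 proportion over 0% (all PS 0-1) and 100%
#' (all PS 2) with age at its reference value.
#'
#' @param fit an `mbma_fit` with covariate terms.
#' @param scenarios named list of named covariate-value lists; `NULL` builds
#'   the default age/PS grid from the fit's terms and reference values.
#' @param n_draws,seed,horizons,include_omega passed to
#'   [simulate_typical_os()].
#' @return data.frame of class `survival_summary`, one row per scenario.
#' @export
subgroup_table <- function(fit, scenarios = NULL, n_draws = 10000, seed = 1,
                           horizons = c(12, 24, 36), include_omega = FALSE) {
  if (is.null(scenarios)) {
    base <- as.list(fit$refs)
    scenarios <- list()
    if ("age_median" %in% fit$term_names) {
      for (a in c(60, 70, 80)) {
        s <- base; s$age_median <- a
        scenarios[[paste0("age_", a)]] <- s
      }
    }
    if ("ps2_pct" %in% fit$term_names) {
      s <- base; s$ps2_pct <- 0
      scenarios[["ps0_1"]] <- s
      s$ps2_pct <- 100
      scenarios[["ps2"]] <- s
    }
    if (!length(scenarios)) scenarios <- list(reference = base)
  }
  rows <- lapply(names(scenarios), function(nm) {
    simulate_typical_os(fit, scenarios[[nm]], n_draws = n_draws, seed = seed,
                        horizons = horizons, include_omega = include_omega,
                        label = nm)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("survival_summary", "data.frame")
  out
}

#' Regimen survival table from pooled corrected hazards
#'
#' Pools the covariate-corrected baseline hazards within each regimen
#' ([pool_regimen()]) and summarises each regimen's typical survival by
#' Monte Carlo simulation from the pooled estimate and its standard error.
#'
#' @param fit an `mbma_fit` of the final model.
#' @param dataset the fitted dataset.
#' @param n_draws,seed,horizons passed to [simulate_typical_os()].
#' @return data.frame of class `survival_summary`, one row per regimen, with
#'   pooling diagnostics (`k`, `tau2`) attached as columns.
#' @export
regimen_table <- function(fit, dataset, n_draws = 10000, seed = 1,
                          horizons = c(12, 24, 36)) {
  corr <- covariate_correct(fit, dataset)
  regs <- intersect(REGIMENS, unique(corr$regimen))
  rows <- lapply(regs, function(rg) {
    pooled <- pool_regimen(corr, rg)
    s <- simulate_typical_os(pooled, n_draws = n_draws, seed = seed,
                             horizons = horizons, label = rg)
    s$k <- pooled$k
    s$tau2 <- pooled$tau2
    s
  })
  out <- do.call(rbind, rows)
  class(out) <- c("survival_summary", "data.frame")
  out
}

#' @export
print.survival_summary <- function(x, ...) {
  fmt <- function(v, lo, hi) sprintf("%.1f (%.1f-%.1f)", v, lo, hi)
  surv_cols <- grep("^surv[0-9]+$", names(x), value = TRUE)
  tab <- data.frame(label = x$label,
                    `MST (months)` = fmt(x$mst, x$mst_lo, x$mst_hi),
                    check.names = FALSE)
  for (sc in surv_cols) {
    h <- sub("surv", "", sc)
    tab[[paste0(h, "-month survival (%)")]] <-
      fmt(x[[sc]], x[[paste0(sc, "_lo")]], x[[paste0(sc, "_hi")]])
  }
  print(tab, row.names = FALSE)
  invisible(x)
}
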