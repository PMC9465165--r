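# Parameter vector layout on the estimation scale:
#   log(beta0), [beta1], theta_1..theta_k, [log(omega)], [log(sigma_eps)]
# beta1 present unless family == "constant"; log(omega) / log(sigma_eps)
# present unless fixed by the caller.
par_layout <- function(family, term_names, omega2_fixed, sigma_fixed) {
  nm <- "log_beta0"
  if (family != "constant") nm <- c(nm, "beta1")
  if (length(term_names)) nm <- c(nm, paste0("theta_", term_names))
  if (is.null(omega2_fixed)) nm <- c(nm, "log_omega")
  if (is.null(sigma_fixed)) nm <- c(nm, "log_sigma")
  nm
}

unpack_params <- function(ph, family, term_names, refs, omega2_fixed,
                          sigma_fixed) {
  ph <- unname(ph)
  i <- 1L
  beta0 <- exp(ph[i]); i <- i + 1L
  beta1 <- 0
  if (family != "constant") { beta1 <- ph[i]; i <- i + 1L }
  theta <- numeric(0)
  if (length(term_names)) {
    theta <- stats::setNames(ph[i:(i + length(term_names) - 1L)], term_names)
    i <- i + length(term_names)
  }
  omega2 <- if (is.null(omega2_fixed)) { o <- exp(ph[i])^2; i <- i + 1L; o
  } else omega2_fixed
  sigma <- if (is.null(sigma_fixed)) exp(ph[i]) else sigma_fixed
  population_params(
    spec = hazard_spec(family, beta0, beta1),
    cov_model = covariate_model(theta, refs[term_names]),
    omega2 = omega2, sigma_eps = sigma)
}

# Objective over prepared units; warm-starts each unit's eta mode across
# evaluations through `state`.
make_objective <- function(pr, family, term_names, omega2_fixed, sigma_fixed) {
  state <- new.env(parent = emptyenv())
  state$eta <- stats::setNames(rep(0, length(pr$groups)), names(pr$groups))
  function(ph) {
    i <- 1L
    lb0 <- ph[i]; i <- i + 1L
    beta1 <- 0
    if (family != "constant") { beta1 <- ph[i]; i <- i + 1L }
    theta <- numeric(length(term_names))
    if (length(term_names)) {
      theta <- ph[i:(i + length(term_names) - 1L)]
      i <- i + length(term_names)
    }
    omega2 <- if (is.null(omega2_fixed)) { o <- exp(2 * ph[i]); i <- i + 1L; o
    } else omega2_fixed
    sigma <- if (is.null(sigma_fixed)) exp(ph[i]) else sigma_fixed
    if (family == "weibull" && beta1 <= -1) return(1e10)
    total <- 0
    for (gn in names(pr$groups)) {
      ua <- pr$arms[pr$groups[[gn]]]
      lam0 <- lapply(ua, function(a) lambda0_fun(family, beta1, a$t))
      lp0 <- vapply(ua, function(a) lb0 + sum(a$x * theta), numeric(1))
      res <- unit_marginal_n2ll(ua, lp0, lam0, sigma^2, omega2,
                                eta_start = state$eta[[gn]])
      if (!is.finite(res$value)) return(1e10)
      state$eta[[gn]] <- res$eta
      total <- total + res$value
    }
    total
  }
}

default_start <- function(pr, family, term_names, omega2_fixed, sigma_fixed) {
  # crude baseline hazard from each arm's last observation
  h <- vapply(pr$arms, function(a) {
    j <- length(a$t)
    s <- min(max(a$obs[j], 0.02), 0.98)
    -log(s) / a$t[j]
  }, numeric(1))
  st <- log(stats::median(h))
  if (family != "constant") st <- c(st, 0)
  st <- c(st, rep(0, length(term_names)))
  if (is.null(omega2_fixed)) st <- c(st, log(0.2))
  if (is.null(sigma_fixed)) st <- c(st, log(1))
  st
}

par_bounds <- function(family, term_names, omega2_fixed, sigma_fixed) {
  lo <- -12; hi <- 3
  if (family != "constant") { lo <- c(lo, if (family == "weibull") -0.95 else -2)
                              hi <- c(hi, 2) }
  lo <- c(lo, rep(-5, length(term_names))); hi <- c(hi, rep(5, length(term_names)))
  if (is.null(omega2_fixed)) { lo <- c(lo, -7); hi <- c(hi, 1.5) }
  if (is.null(sigma_fixed)) { lo <- c(lo, -6); hi <- c(hi, 3) }
  list(lower = lo, upper = hi)
}

#' Fit the nonlinear mixed-effects survival meta-model
#'
#' Maximises the Laplace-approximated marginal likelihood over
#' (log baseline hazard, shape if the family has one, covariate coefficients,
#' log inter-study SD, log residual scale) with `nlminb`, restarting from
#' jittered points on failure. The covariance of the estimates is the inverse
#' Hessian (finite differences, relative step 1e-4) of half the objective at
#' the optimum; relative standard errors are reported on the natural scale
#' via the delta method; per-arm empirical-Bayes effects are returned with
#' their curvatures.
#'
#' @param dataset an `mbma_dataset`; SEs are resolved automatically.
#' @param family hazard family, see [hazard_spec()].
#' @param covariate_terms character vector of arm covariate columns entering
#'   the baseline hazard (centred).
#' @param cov_refs optional named reference (centring) values; defaults to
#'   the dataset medians across arms.
#' @param eta_level random-effect unit, `"arm"` (default) or `"study"`.
#' @param omega2 fix the inter-study variance at this value (e.g. 0) instead
#'   of estimating it; `NULL` (default) estimates it.
#' @param sigma_eps fix the residual scale instead of estimating it.
#' @param start optional start vector on the estimation scale.
#' @param control passed to [stats::nlminb()]; OFV convergence tolerance
#'   defaults to 1e-8.
#' @return an object of class `mbma_fit`.
#' @export
fit_model <- function(dataset, family = "constant",
                      covariate_terms = character(0), cov_refs = NULL,
                      eta_level = "arm", omega2 = NULL, sigma_eps = NULL,
                      start = NULL, control = list()) {
  stopifnot(inherits(dataset, "mbma_dataset"))
  dataset <- resolve_se(dataset)
  term_names <- covariate_terms
  refs <- if (is.null(cov_refs)) {
    vapply(term_names, function(nm) stats::median(dataset$arms[[nm]]),
           numeric(1))
  } else {
    stopifnot(all(term_names %in% names(cov_refs)))
    cov_refs[term_names]
  }
  if (length(term_names) == 0) refs <- numeric(0)
  pr <- prep_units(dataset, term_names, refs, eta_level)
  obj <- make_objective(pr, family, term_names, omega2, sigma_eps)
  pnames <- par_layout(family, term_names, omega2, sigma_eps)
  bounds <- par_bounds(family, term_names, omega2, sigma_eps)
  ctrl <- utils::modifyList(list(rel.tol = 1e-10, abs.tol = 1e-8,
                                 iter.max = 500, eval.max = 1000), control)

  st <- if (is.null(start)) default_start(pr, family, term_names, omega2,
                                          sigma_eps) else start
  fits <- list()
  converged <- FALSE
  for (attempt in 1:4) {
    op <- tryCatch(
      stats::nlminb(st, obj, lower = bounds$lower, upper = bounds$upper,
                    control = ctrl),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$objective)) {
      fits[[length(fits) + 1L]] <- op
      if (op$convergence == 0) { converged <- TRUE; break }
    }
    # jittered restart (deterministic per attempt)
    jit <- withr_seed_jitter(attempt, length(st))
    st <- pmin(pmax(st + jit, bounds$lower), bounds$upper)
  }
  if (!length(fits)) {
    return(structure(list(converged = FALSE, family = family,
                          message = "all optimisation attempts failed"),
                     class = "mbma_fit"))
  }
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  ph <- stats::setNames(best$par, pnames)
  params <- unpack_params(ph, family, term_names, refs, omega2, sigma_eps)
  ofv <- best$objective

  # covariance = inverse Hessian of the -log marginal likelihood (= OFV/2)
  H <- tryCatch(hessian_fd(obj, best$par), error = function(e) NULL)
  covar <- NULL
  if (!is.null(H)) {
    covar <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(covar) && any(diag(covar) <= 0)) covar <- NULL
    if (is.null(covar)) warning("singular or non-positive-definite Hessian; ",
                                "covariance unavailable")
  }
  if (!is.null(covar)) dimnames(covar) <- list(pnames, pnames)

  est <- natural_estimates(ph, params, term_names, omega2, sigma_eps)
  se_nat <- rse <- ci_lo <- ci_hi <- rep(NA_real_, length(est))
  names(se_nat) <- names(rse) <- names(ci_lo) <- names(ci_hi) <- names(est)
  if (!is.null(covar)) {
    se_ph <- sqrt(diag(covar))
    se_nat <- delta_se(ph, se_ph, names(est))
    rse <- 100 * se_nat / abs(est)
    ci_lo <- est - 1.96 * se_nat
    ci_hi <- est + 1.96 * se_nat
  }

  # empirical-Bayes effects per unit, mapped to arms
  eta_hat <- stats::setNames(rep(0, pr$n_arms), names(pr$arms))
  eta_curv <- stats::setNames(rep(Inf, pr$n_arms), names(pr$arms))
  if (params$omega2 > 0) {
    for (gn in names(pr$groups)) {
      idx <- pr$groups[[gn]]
      ua <- pr$arms[idx]
      lam0 <- lapply(ua, function(a) {
        lambda0_fun(family, params$spec$beta1, a$t)
      })
      lp0 <- vapply(ua, function(a) {
        log(params$spec$beta0) + sum(a$x * params$cov_model$terms)
      }, numeric(1))
      m <- find_eta_mode(ua, lp0, lam0, params$sigma_eps^2, params$omega2)
      eta_hat[idx] <- m$eta
      eta_curv[idx] <- m$hess
    }
  }

  structure(list(
    params = params, family = family, ofv = ofv,
    estimates = est, se = se_nat, rse_pct = rse,
    ci = cbind(lower = ci_lo, upper = ci_hi),
    covariance = covar, par = ph, par_names = pnames,
    eta_hat = eta_hat, eta_curvature = eta_curv,
    converged = converged, n_arms = pr$n_arms, n_obs = pr$n_obs,
    eta_level = pr$eta_level, refs = refs, term_names = term_names,
    omega2_fixed = omega2, sigma_fixed = sigma_eps,
    dataset_arm_ids = names(pr$arms)), class = "mbma_fit")
}

# central-difference Hessian with per-coordinate relative step
hessian_fd <- function(f, x, rel = 1e-4) {
  k <- length(x)
  h <- pmax(abs(x), 1) * rel
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) for (j in (i + 1):k) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# deterministic jitter for restarts, independent of the caller's RNG state
withr_seed_jitter <- function(attempt, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(1000 + attempt)
  stats::rnorm(k, 0, 0.3)
}

natural_estimates <- function(ph, params, term_names, omega2_fixed,
                              sigma_fixed) {
  est <- c(beta0 = unname(params$spec$beta0))
  if (params$spec$family != "constant") est <- c(est, beta1 = params$spec$beta1)
  if (length(term_names)) {
    est <- c(est, stats::setNames(as.numeric(params$cov_model$terms),
                                  paste0("theta_", term_names)))
  }
  if (is.null(omega2_fixed)) est <- c(est, omega = sqrt(params$omega2))
  if (is.null(sigma_fixed)) est <- c(est, sigma_eps = params$sigma_eps)
  est
}

# delta-method SEs on the natural scale: log-scale parameters map through
# exp, so SE_nat = exp(est_log) * SE_log; identity-scale parameters pass
# through unchanged.
delta_se <- function(ph, se_ph, nat_names) {
  out <- numeric(length(nat_names))
  names(out) <- nat_names
  j <- 1L
  for (nm in names(ph)) {
    if (startsWith(nm, "log_")) {
      out[j] <- exp(ph[[nm]]) * se_ph[[nm]]
    } else {
      out[j] <- se_ph[[nm]]
    }
    j <- j + 1L
  }
  out
}

#' @export
print.mbma_fit <- function(x, digits = 3, ...) {
  if (!isTRUE(x$converged) && is.null(x$estimates)) {
    cat("<mbma_fit> NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<mbma_fit> family=%s  arms=%d  obs=%d  OFV=%.3f%s\n",
              x$family, x$n_arms, x$n_obs, x$ofv,
              if (x$converged) "" else "  [not converged]"))
  tab <- data.frame(
    `Value (RSE%)` = sprintf("%.*g (%.1f)", digits, x$estimates, x$rse_pct),
    `95% CI` = sprintf("%.*g-%.*g", digits, x$ci[, 1], digits, x$ci[, 2]),
    check.names = FALSE, row.names = names(x$estimates))
  print(tab)
  if (length(x$term_names)) {
    cat("centred at:",
        paste(sprintf("%s=%g", x$term_names, x$refs[x$term_names]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parameter table of a fitted model
#'
#' Estimates with RSE% and Wald 95% confidence intervals
#' (estimate +/- 1.96 * SE on the natural scale).
#'
#' @param fit an `mbma_fit`.
#' @return data.frame with columns parameter, estimate, se, rse_pct, ci_lower,
#'   ci_upper.
#' @export
fit_parameter_table <- function(fit) {
  stopifnot(inherits(fit, "mbma_fit"))
  data.frame(parameter = names(fit$estimates),
             estimate = as.numeric(fit$estimates),
             se = as.numeric(fit$se),
             rse_pct = as.numeric(fit$rse_pct),
             ci_lower = as.numeric(fit$ci[, 1]),
             ci_upper = as.numeric(fit$ci[, 2]),
             row.names = NULL)
}

#' Write a fit report as JSON
#'
#' Estimates, RSE%, confidence intervals, OFV and the empirical-Bayes table,
#' serialised for downstream stages.
#'
#' @param fit an `mbma_fit`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "mbma_fit"))
  rep <- list(family = fit$family, ofv = fit$ofv, converged = fit$converged,
              n_arms = fit$n_arms, n_obs = fit$n_obs,
              parameters = fit_parameter_table(fit),
              centring = as.list(fit$refs),
              eta_hat = as.list(fit$eta_hat))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Compare the three hazard families on a dataset
#'
#' Fits the constant, Gompertz and Weibull hazard families without covariates
#' and ranks them. The primary ranking is AIC-style (OFV + 2 * number of
#' estimated parameters, which breaks OFV ties in favour of the
#' fewer-parameter family); a plain OFV ranking is also reported. A family
#' that fails to converge is kept in the table and flagged.
#'
#' @param dataset an `mbma_dataset`.
#' @param eta_level passed to [fit_model()].
#' @param ... further arguments to [fit_model()].
#' @return data.frame (family, ofv, n_params, aic, converged, rank_aic,
#'   rank_ofv), ordered by the AIC-style rank; the fits themselves are in
#'   `attr(, "fits")`.
#' @export
compare_families <- function(dataset, eta_level = "arm", ...) {
  fams <- c("constant", "gompertz", "weibull")
  fits <- lapply(fams, function(f) {
    fit_model(dataset, family = f, eta_level = eta_level, ...)
  })
  names(fits) <- fams
  np <- vapply(fits, function(f) length(f$par), numeric(1))
  ofv <- vapply(fits, function(f) if (is.null(f$ofv)) Inf else f$ofv, numeric(1))
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  aic <- ofv + 2 * np
  tab <- data.frame(family = fams, ofv = ofv, n_params = np, aic = aic,
                    converged = conv, row.names = NULL)
  # AIC primary, then fewer parameters on exact ties
  ord <- order(tab$aic, tab$n_params)
  tab$rank_aic <- match(seq_len(nrow(tab)), ord)
  tab$rank_ofv <- match(seq_len(nrow(tab)), order(tab$ofv, tab$n_params))
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
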