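# Internal prepared representation of a dataset for likelihood work.
#
# Each random-effect unit (one arm, or one study when eta_level = "study")
# carries, per member arm: observation times, observed survival, resolved SEs,
# and the centred covariate vector. The baseline hazard enters every family
# multiplicatively, so S(t) = exp(-beta_i * lambda0(t)) where lambda0 is the
# unit-baseline cumulative hazard; lambda0 depends only on (family, beta1)
# and is recomputed per objective evaluation, not per eta evaluation.
prep_units <- function(dataset, term_names, refs,
                       eta_level = c("arm", "study")) {
  eta_level <- match.arg(eta_level)
  dataset <- resolve_se(dataset)
  arms <- dataset$arms
  cur <- dataset$curves
  miss <- setdiff(term_names, names(arms))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  arm_list <- lapply(seq_len(nrow(arms)), function(i) {
    d <- cur[cur$arm_id == arms$arm_id[i], , drop = FALSE]
    x <- if (length(term_names)) {
      as.numeric(unlist(arms[i, term_names])) - refs[term_names]
    } else numeric(0)
    list(arm_id = arms$arm_id[i], t = d$time_months, obs = d$survival,
         se = d$se, x = x,
         # per-arm additive constant of the -2 log-likelihood
         kconst = sum(log(2 * pi * d$se^2)), n = nrow(d))
  })
  names(arm_list) <- arms$arm_id
  key <- if (eta_level == "study") arms$study_id else arms$arm_id
  groups <- split(seq_len(nrow(arms)), factor(key, levels = unique(key)))
  list(arms = arm_list, groups = groups, n_obs = nrow(cur),
       n_arms = nrow(arms), eta_level = eta_level)
}

# Unit-baseline cumulative hazard Lambda0(t) (beta0 = 1) per family.
lambda0_fun <- function(family, beta1, t) {
  switch(family,
    constant = t,
    gompertz = if (abs(beta1) < 1e-8) {
      t + beta1 * t^2 / 2 + beta1^2 * t^3 / 6
    } else (exp(beta1 * t) - 1) / beta1,
    weibull = t^(beta1 + 1) / (beta1 + 1)
  )
}

# Conditional -2 log-likelihood of one unit at a given eta, with analytic
# first and second derivatives in eta. theta, log-beta0 etc. enter through
# `lp0` = log(beta_typical) + x'theta per arm, precomputed by the caller.
# Returns list(value, grad, hess).
unit_n2ll_eta <- function(unit_arms, lp0, lam0, eta, sigma2, omega2,
                          with_prior = TRUE, deriv = TRUE) {
  val <- 0; gr <- 0; he <- 0
  for (k in seq_along(unit_arms)) {
    a <- unit_arms[[k]]
    beta_i <- exp(lp0[k] + eta)
    bl <- beta_i * lam0[[k]]
    pred <- exp(-bl)
    r <- (a$obs - pred) / a$se
    val <- val + sum(r^2) / sigma2 + a$kconst + a$n * log(sigma2)
    if (deriv) {
      dp <- -bl * pred                       # d pred / d eta
      d2p <- bl * pred * (bl - 1)            # d2 pred / d eta2
      dr <- -dp / a$se
      d2r <- -d2p / a$se
      gr <- gr + (2 / sigma2) * sum(r * dr)
      he <- he + (2 / sigma2) * sum(dr^2 + r * d2r)
    }
  }
  if (with_prior) {
    if (omega2 <= 0) stop("degenerate prior: omega2 = 0 with free eta")
    val <- val + eta^2 / omega2 + log(2 * pi * omega2)
    gr <- gr + 2 * eta / omega2
    he <- he + 2 / omega2
  }
  list(value = val, grad = gr, hess = he)
}

# Posterior mode of eta for one unit: safeguarded Newton on the conditional
# -2 log-likelihood, falling back to golden-section search if curvature
# misbehaves. Returns list(eta, value, hess).
find_eta_mode <- function(unit_arms, lp0, lam0, sigma2, omega2, eta_start = 0) {
  f <- function(e, deriv = TRUE) {
    unit_n2ll_eta(unit_arms, lp0, lam0, e, sigma2, omega2, deriv = deriv)
  }
  eta <- eta_start
  cur <- f(eta)
  for (it in 1:50) {
    if (!is.finite(cur$value)) { eta <- 0; cur <- f(eta); next }
    if (cur$hess > 1e-10) {
      step <- -cur$grad / cur$hess
    } else {
      step <- -sign(cur$grad) * 0.5
    }
    step <- max(min(step, 1), -1)
    if (abs(step) < 1e-10) break
    new_eta <- eta + step
    new <- f(new_eta)
    tries <- 0
    while ((!is.finite(new$value) || new$value > cur$value + 1e-12) &&
           tries < 30) {
      step <- step / 2
      new_eta <- eta + step
      new <- f(new_eta)
      tries <- tries + 1
    }
    if (!is.finite(new$value) || new$value > cur$value) break
    conv <- abs(new$value - cur$value) < 1e-12 && abs(step) < 1e-8
    eta <- new_eta; cur <- new
    if (conv) break
  }
  if (cur$hess <= 0) {
    # fall back to derivative-free search around the current point
    opt <- stats::optimize(function(e) f(e, deriv = FALSE)$value,
                           c(eta - 2, eta + 2), tol = 1e-10)
    eta <- opt$minimum
    cur <- f(eta)
  }
  list(eta = eta, value = cur$value, hess = cur$hess)
}

# -2 log marginal likelihood of one unit.
# Laplace: g(eta_hat) + log(g''(eta_hat) / (4*pi)), where g is the
# conditional -2 log joint (data + prior); this equals
# -2 log[ exp(-g/2) * sqrt(2*pi / (g''/2)) ].
# AGHQ: adaptive Gauss-Hermite with `nodes` nodes centred at the mode with
# scale sqrt(2/g'').
unit_marginal_n2ll <- function(unit_arms, lp0, lam0, sigma2, omega2,
                               method = "laplace", nodes = 64,
                               eta_start = 0) {
  if (omega2 <= 0) {
    v <- unit_n2ll_eta(unit_arms, lp0, lam0, 0, sigma2, omega2,
                       with_prior = FALSE, deriv = FALSE)$value
    return(list(value = v, eta = 0, hess = Inf))
  }
  m <- find_eta_mode(unit_arms, lp0, lam0, sigma2, omega2, eta_start)
  if (method == "laplace") {
    val <- m$value + log(m$hess / (4 * pi))
  } else {
    gh <- pracma::gaussHermite(nodes)
    s <- sqrt(2 / m$hess)
    z <- m$eta + sqrt(2) * s * gh$x
    gz <- vapply(z, function(e) {
      unit_n2ll_eta(unit_arms, lp0, lam0, e, sigma2, omega2,
                    deriv = FALSE)$value
    }, numeric(1))
    # integral = sqrt(2)*s * sum w_k exp(x_k^2) exp(-(g(z_k))/2)
    lsum <- log(sum(gh$w * exp(gh$x^2 - (gz - m$value) / 2)))
    val <- m$value - 2 * (lsum + log(sqrt(2) * s))
  }
  list(value = val, eta = m$eta, hess = m$hess)
}

#' Conditional -2 log-likelihood of one arm given its inter-study effect
#'
#' The weighted Gaussian residual deviance of an arm's survival observations
#' plus the Gaussian prior deviance of \eqn{\eta}:
#' \deqn{\sum_j \left[\left(\frac{obs_j - S(t_j;\beta_i)}{se_j\,\sigma_\epsilon}\right)^2
#'   + \ln\{2\pi (se_j \sigma_\epsilon)^2\}\right]
#'   + \frac{\eta^2}{\omega^2} + \ln(2\pi\omega^2),}
#' with \eqn{\beta_i} from [apply_covariates()]. With `omega2 = 0` the prior
#' terms are dropped (and a nonzero `eta` is an error).
#'
#' @param params a [population_params()].
#' @param eta inter-study effect for this arm.
#' @param arm one-row data.frame (or named list) with the arm's covariates.
#' @param curve data.frame with time_months, survival and resolved se.
#' @return scalar deviance contribution.
#' @export
conditional_neg2ll <- function(params, eta, arm, curve) {
  stopifnot(inherits(params, "population_params"))
  if (anyNA(curve$se)) stop("SEs must be resolved (see resolve_se)")
  if (params$omega2 <= 0 && eta != 0) {
    stop("degenerate prior: omega2 = 0 requires eta = 0")
  }
  tn <- names(params$cov_model$terms)
  x <- if (length(tn)) as.numeric(unlist(arm[tn])) - params$cov_model$refs[tn] else numeric(0)
  ua <- list(list(arm_id = "a", t = curve$time_months, obs = curve$survival,
                  se = curve$se, x = x,
                  kconst = sum(log(2 * pi * curve$se^2)), n = nrow(curve)))
  lam0 <- list(lambda0_fun(params$spec$family, params$spec$beta1,
                           curve$time_months))
  lp0 <- log(params$spec$beta0) + sum(x * params$cov_model$terms)
  unit_n2ll_eta(ua, lp0, lam0, eta, params$sigma_eps^2, params$omega2,
                with_prior = params$omega2 > 0, deriv = FALSE)$value
}

#' Marginal objective function value (-2 log marginal likelihood)
#'
#' Sums, over random-effect units, \eqn{-2\ln \int L(unit \mid \eta)\,
#' \varphi(\eta; 0, \omega^2)\, d\eta}. The integral is Laplace-approximated
#' at the empirical-Bayes mode by default; `method = "aghq"` uses adaptive
#' Gauss-Hermite quadrature instead (the testing oracle). With
#' `omega2 = 0` there is no random effect to integrate and the conditional
#' deviance at \eqn{\eta = 0} (without prior terms) is returned.
#'
#' @param params a [population_params()].
#' @param dataset an `mbma_dataset` (SEs resolved automatically).
#' @param method `"laplace"` or `"aghq"`.
#' @param nodes number of quadrature nodes for `"aghq"`.
#' @param eta_level random-effect unit: `"arm"` (default) or `"study"`.
#' @return scalar OFV, deterministic given inputs.
#' @export
marginal_ofv <- function(params, dataset, method = c("laplace", "aghq"),
                         nodes = 64, eta_level = "arm") {
  method <- match.arg(method)
  stopifnot(inherits(params, "population_params"))
  tn <- names(params$cov_model$terms)
  pr <- prep_units(dataset, tn, params$cov_model$refs, eta_level)
  total <- 0
  for (g in pr$groups) {
    ua <- pr$arms[g]
    lam0 <- lapply(ua, function(a) {
      lambda0_fun(params$spec$family, params$spec$beta1, a$t)
    })
    lp0 <- vapply(ua, function(a) {
      log(params$spec$beta0) + sum(a$x * params$cov_model$terms)
    }, numeric(1))
    res <- unit_marginal_n2ll(ua, lp0, lam0, params$sigma_eps^2,
                              params$omega2, method, nodes)
    if (!is.finite(res$value)) {
      stop("non-finite objective at the supplied parameter values; ",
           "consider rescaling the starting values")
    }
    total <- total + res$value
  }
  total
}

#' Empirical-Bayes (Bayesian feedback) estimate of an arm's eta
#'
#' Posterior mode of the inter-study effect for one arm under fitted
#' population parameters, with the curvature (second derivative of the
#' conditional -2 log joint at the mode) used as the Laplace weight; the
#' approximate posterior variance of \eqn{\hat\eta} is `2 / curvature`.
#' As \eqn{\omega^2 \to 0} the mode shrinks to 0.
#'
#' @param params a [population_params()].
#' @param arm one-row data.frame with the arm's covariates.
#' @param curve data.frame with time_months, survival and resolved se.
#' @return list with `eta_hat` and `curvature`.
#' @export
empirical_bayes_eta <- function(params, arm, curve) {
  stopifnot(inherits(params, "population_params"))
  if (anyNA(curve$se)) stop("SEs must be resolved (see resolve_se)")
  if (params$omega2 <= 0) return(list(eta_hat = 0, curvature = Inf))
  tn <- names(params$cov_model$terms)
  x <- if (length(tn)) as.numeric(unlist(arm[tn])) - params$cov_model$refs[tn] else numeric(0)
  ua <- list(list(arm_id = "a", t = curve$time_months, obs = curve$survival,
                  se = curve$se, x = x,
                  kconst = sum(log(2 * pi * curve$se^2)), n = nrow(curve)))
  lam0 <- list(lambda0_fun(params$spec$family, params$spec$beta1,
                           curve$time_months))
  lp0 <- log(params$spec$beta0) + sum(x * params$cov_model$terms)
  m <- find_eta_mode(ua, lp0, lam0, params$sigma_eps^2, params$omega2)
  list(eta_hat = m$eta, curvature = m$hess)
}
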