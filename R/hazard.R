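#' Parametric hazard model specification
#'
#' Constructs the specification of a parametric proportional-hazard model for
#' aggregate overall-survival curves. Three hazard shapes are supported:
#' constant \eqn{h(t) = \beta_0}, Gompertz \eqn{h(t) = \beta_0 e^{\beta_1 t}},
#' and Weibull \eqn{h(t) = \beta_0 e^{\beta_1 \ln t} = \beta_0 t^{\beta_1}}.
#' \eqn{\beta_0} is the initial death risk per month at the start of
#' treatment; \eqn{\beta_1} is a unitless shape parameter (ignored for the
#' constant family).
#'
#' @param family one of `"constant"`, `"gompertz"`, `"weibull"`.
#' @param beta0 initial death risk per month; must be positive.
#' @param beta1 shape parameter; for the Weibull family it must exceed -1 so
#'   the cumulative hazard converges at the time origin.
#' @return an object of class `hazard_spec`.
#' @export
hazard_spec <- function(family = c("constant", "gompertz", "weibull"),
                        beta0, beta1 = 0) {
  family <- match.arg(family)
  if (!is.numeric(beta0) || length(beta0) != 1L || !is.finite(beta0) ||
      beta0 <= 0) {
    stop("beta0 must be a single positive number, got ", format(beta0))
  }
  if (!is.numeric(beta1) || length(beta1) != 1L || !is.finite(beta1)) {
    stop("beta1 must be a single finite number")
  }
  if (family == "weibull" && beta1 <= -1) {
    stop("Weibull shape beta1 must be > -1 (cumulative hazard diverges at 0)")
  }
  structure(list(family = family, beta0 = beta0, beta1 = beta1),
            class = "hazard_spec")
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat(sprintf("<hazard_spec> family=%s beta0=%g", x$family, x$beta0))
  if (x$family != "constant") cat(sprintf(" beta1=%g", x$beta1))
  cat("\n")
  invisible(x)
}

#' Instantaneous hazard
#'
#' Death risk per month at time `t` under a parametric hazard specification.
#'
#' @param spec a [hazard_spec()].
#' @param t time in months (vectorised); must be non-negative, and strictly
#'   positive for the Weibull family with a negative shape.
#' @return hazard rate(s) per month.
#' @export
hazard <- function(spec, t) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (any(t < 0)) stop("t must be non-negative")
  switch(spec$family,
    constant = rep_len(spec$beta0, length(t)),
    gompertz = spec$beta0 * exp(spec$beta1 * t),
    weibull = {
      if (any(t == 0) && spec$beta1 < 0) {
        stop("Weibull hazard with beta1 < 0 is undefined at t = 0")
      }
      spec$beta0 * t^spec$beta1
    }
  )
}

#' Cumulative hazard over an interval
#'
#' Closed-form integral of the hazard from `t0` to `t`:
#' constant \eqn{\beta_0 (t - t_0)};
#' Gompertz \eqn{(\beta_0/\beta_1)(e^{\beta_1 t} - e^{\beta_1 t_0})}, with a
#' series expansion near \eqn{\beta_1 = 0} to avoid cancellation;
#' Weibull \eqn{\beta_0 (t^{\beta_1+1} - t_0^{\beta_1+1})/(\beta_1+1)}.
#'
#' @param spec a [hazard_spec()].
#' @param t0 interval start in months (scalar or vectorised with `t`).
#' @param t interval end in months; `t >= t0` required.
#' @return cumulative hazard(s), non-negative, additive over adjoining
#'   intervals.
#' @export
cumulative_hazard <- function(spec, t0, t) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (any(t0 < 0) || any(t < t0)) stop("need 0 <= t0 <= t")
  b0 <- spec$beta0
  b1 <- spec$beta1
  switch(spec$family,
    constant = b0 * (t - t0),
    gompertz = {
      if (abs(b1) < 1e-8) {
        # second-order expansion of (e^{b1 t} - e^{b1 t0})/b1
        b0 * ((t - t0) + b1 * (t^2 - t0^2) / 2 + b1^2 * (t^3 - t0^3) / 6)
      } else {
        (b0 / b1) * (exp(b1 * t) - exp(b1 * t0))
      }
    },
    weibull = {
      if (b1 <= -1) stop("Weibull shape beta1 must be > -1")
      b0 * (t^(b1 + 1) - t0^(b1 + 1)) / (b1 + 1)
    }
  )
}

#' Survival function
#'
#' \eqn{S(t) = e^{-\Lambda(0, t)}}; equals 1 at \eqn{t = 0} and is
#' non-increasing in `t` for any valid specification.
#'
#' @inheritParams hazard
#' @return survival probability/probabilities in (0, 1].
#' @export
survival_prob <- function(spec, t) {
  exp(-cumulative_hazard(spec, 0, t))
}

#' Median survival time
#'
#' Time at which the survival function crosses 0.5. Exact
#' (\eqn{\ln 2 / \beta_0}) for the constant family; otherwise solved
#' numerically to an absolute tolerance of 1e-8 months.
#'
#' @param spec a [hazard_spec()].
#' @return median survival time in months.
#' @export
median_survival_time <- function(spec) {
  if (spec$family == "constant") return(log(2) / spec$beta0)
  f <- function(t) cumulative_hazard(spec, 0, t) - log(2)
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Covariate model for the baseline hazard
#'
#' An ordered set of continuous covariate terms entering the baseline hazard
#' multiplicatively on the log scale, each centred at a stored reference value
#' (the dataset median at model-building time):
#' \deqn{\beta_i = \beta_{typical} \exp\{\sum_k (COV_{ik} - ref_k)\theta_k + \eta_i\}.}
#'
#' @param terms named numeric vector of coefficients \eqn{\theta} (names are
#'   covariate names); may be empty.
#' @param refs named numeric vector of reference (centring) values, same names.
#' @return an object of class `covariate_model`.
#' @export
covariate_model <- function(terms = numeric(0), refs = numeric(0)) {
  if (length(terms)) {
    if (is.null(names(terms)) || anyDuplicated(names(terms))) {
      stop("covariate terms must have unique names")
    }
    if (!setequal(names(terms), names(refs))) {
      stop("terms and refs must cover the same covariate names")
    }
    refs <- refs[names(terms)]
  }
  structure(list(terms = terms, refs = refs), class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, ...) {
  if (!length(x$terms)) {
    cat("<covariate_model> (no terms)\n")
  } else {
    cat("<covariate_model>\n")
    for (nm in names(x$terms)) {
      cat(sprintf("  %s: theta=%g ref=%g\n", nm, x$terms[[nm]], x$refs[[nm]]))
    }
  }
  invisible(x)
}

#' Covariate multiplier for one arm
#'
#' \eqn{\exp\{\sum_k (COV_k - ref_k)\theta_k\}} evaluated at an arm's
#' covariate values; the inter-study effect \eqn{\eta} is excluded.
#'
#' @param cov_model a [covariate_model()].
#' @param cov_values named list/vector holding every term's covariate value.
#' @return positive scalar multiplier.
#' @export
covariate_multiplier <- function(cov_model, cov_values) {
  stopifnot(inherits(cov_model, "covariate_model"))
  if (!length(cov_model$terms)) return(1)
  missing <- setdiff(names(cov_model$terms), names(cov_values))
  if (length(missing)) {
    stop("missing covariate value(s): ", paste(missing, collapse = ", "))
  }
  v <- vapply(names(cov_model$terms), function(nm) as.numeric(cov_values[[nm]]),
              numeric(1))
  exp(sum((v - cov_model$refs) * cov_model$terms))
}

#' Individual baseline hazard from covariates and inter-study effect
#'
#' Applies the covariate model and the arm-level random effect to the typical
#' baseline hazard:
#' \eqn{\beta_i = \beta_{typical}\exp\{\sum_k (COV_k - ref_k)\theta_k + \eta\}}.
#' At the reference covariate values with \eqn{\eta = 0} this is the identity
#' on `beta_typical`.
#'
#' @param beta_typical typical baseline hazard (per month).
#' @param cov_model a [covariate_model()].
#' @param cov_values named values containing every term's covariate.
#' @param eta arm-level inter-study effect on the log scale.
#' @return individual baseline hazard.
#' @export
apply_covariates <- function(beta_typical, cov_model, cov_values, eta = 0) {
  beta_typical * covariate_multiplier(cov_model, cov_values) * exp(eta)
}
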