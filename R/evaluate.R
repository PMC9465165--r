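# predictions at the observed design for given population params, one row
# per curve point: population (eta = 0) and individual (eta = eta_hat)
predict_design <- function(params, dataset, eta = NULL) {
  dataset <- resolve_se(dataset)
  arms <- dataset$arms
  out <- dataset$curves
  out$pred <- NA_real_
  for (i in seq_len(nrow(arms))) {
    sel <- out$arm_id == arms$arm_id[i]
    e <- if (is.null(eta)) 0 else eta[[as.character(arms$arm_id[i])]]
    beta_i <- apply_covariates(params$spec$beta0, params$cov_model,
                               arms[i, ], e)
    spec_i <- hazard_spec(params$spec$family, beta_i, params$spec$beta1)
    out$pred[sel] <- survival_prob(spec_i, out$time_months[sel])
  }
  out
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset's observations at the observed
#' design (times, covariates, standard errors): each replicate draws one
#' inter-study effect per random-effect unit from \eqn{N(0, \hat\omega^2)}
#' and one residual per point from \eqn{N(0, (se\,\hat\sigma_\epsilon)^2)}.
#' Pointwise 2.5/50/97.5 percentiles across replicates form the prediction
#' bands; coverage is the fraction of observed points inside the 95% band.
#' Simulated observations are not truncated to \[0, 1\] for the band
#' computation (the residual model is additive); truncate for plotting only.
#'
#' @param fit an `mbma_fit`, or a [population_params()] to check a model with
#'   known parameters.
#' @param dataset the dataset whose design (and observations) to use.
#' @param n_sim number of simulation replicates; fewer than 100 triggers a
#'   warning about unstable percentiles.
#' @param seed integer seed (the result is deterministic given it).
#' @param eta_level random-effect unit.
#' @return list of class `mbma_vpc` with `table` (per-point observed value,
#'   band, inside flag, regimen, arm size) and `coverage`.
#' @export
visual_predictive_check <- function(fit, dataset, n_sim = 1000, seed = 1,
                                    eta_level = "arm") {
  params <- if (inherits(fit, "mbma_fit")) fit$params else fit
  stopifnot(inherits(params, "population_params"))
  if (n_sim < 100) warning("n_sim < 100: percentile bands will be unstable")
  dataset <- resolve_se(dataset)
  arms <- dataset$arms
  cur <- dataset$curves
  set.seed(seed)
  key <- if (eta_level == "study") arms$study_id else arms$arm_id
  units <- unique(key)
  eta_draws <- matrix(stats::rnorm(length(units) * n_sim, 0,
                                   sqrt(params$omega2)),
                      nrow = length(units), dimnames = list(units, NULL))
  lo <- med <- hi <- numeric(nrow(cur))
  for (i in seq_len(nrow(arms))) {
    sel <- which(cur$arm_id == arms$arm_id[i])
    t <- cur$time_months[sel]
    se <- cur$se[sel]
    beta_base <- apply_covariates(params$spec$beta0, params$cov_model,
                                  arms[i, ], 0)
    lam0 <- lambda0_fun(params$spec$family, params$spec$beta1, t)
    beta_sim <- beta_base * exp(eta_draws[key[i], ])       # length n_sim
    pred <- exp(-outer(lam0, beta_sim))                    # n_t x n_sim
    obs_sim <- pred + se * params$sigma_eps *
      matrix(stats::rnorm(length(t) * n_sim), nrow = length(t))
    qs <- apply(obs_sim, 1, stats::quantile, probs = c(0.025, 0.5, 0.975))
    lo[sel] <- qs[1, ]; med[sel] <- qs[2, ]; hi[sel] <- qs[3, ]
  }
  n_by_arm <- stats::setNames(arms$n, arms$arm_id)
  reg_by_arm <- stats::setNames(arms$regimen, arms$arm_id)
  tab <- data.frame(arm_id = cur$arm_id,
                    regimen = reg_by_arm[as.character(cur$arm_id)],
                    n = n_by_arm[as.character(cur$arm_id)],
                    time_months = cur$time_months, observed = cur$survival,
                    band_lower = lo, predicted_median = med, band_upper = hi,
                    row.names = NULL)
  tab$inside <- tab$observed >= tab$band_lower & tab$observed <= tab$band_upper
  structure(list(table = tab, coverage = mean(tab$inside), n_sim = n_sim,
                 seed = seed), class = "mbma_vpc")
}

#' @export
print.mbma_vpc <- function(x, ...) {
  cat(sprintf("<mbma_vpc> %d points, %d replicates, 95%%-band coverage %.3f\n",
              nrow(x$table), x$n_sim, x$coverage))
  invisible(x)
}

#' Goodness-of-fit table
#'
#' One row per observation with the population prediction (\eqn{\eta = 0}),
#' the individual prediction (empirical-Bayes \eqn{\hat\eta}), and the
#' weighted residual \eqn{(obs - pred_{ind}) / (se\,\hat\sigma_\epsilon)}.
#'
#' @param fit an `mbma_fit`.
#' @param dataset the fitted dataset.
#' @return data.frame (arm_id, time_months, observed, pred_population,
#'   pred_individual, weighted_residual).
#' @export
goodness_of_fit <- function(fit, dataset) {
  stopifnot(inherits(fit, "mbma_fit"))
  dataset <- resolve_se(dataset)
  pop <- predict_design(fit$params, dataset)
  ind <- predict_design(fit$params, dataset, eta = fit$eta_hat)
  data.frame(arm_id = pop$arm_id, time_months = pop$time_months,
             observed = pop$survival, pred_population = pop$pred,
             pred_individual = ind$pred,
             weighted_residual = (pop$survival - ind$pred) /
               (pop$se * fit$params$sigma_eps),
             row.names = NULL)
}

#' Leave-one-out cross-validation of the model
#'
#' Drops one unit at a time (by default a whole study, so multi-arm studies
#' leave together), refits the model on the remaining data, and tabulates the
#' per-fold parameter estimates together with min/max/median per parameter
#' for the stability report.
#'
#' @param dataset an `mbma_dataset` with at least 3 units.
#' @param family hazard family.
#' @param covariate_terms covariate columns of the final model.
#' @param by `"study"` (default) or `"arm"`.
#' @param cov_refs optional centring values; defaults to full-dataset medians
#'   so every fold is fitted with the same centring.
#' @param ... further arguments to [fit_model()].
#' @return list with `folds` (data.frame of per-fold estimates, plus a
#'   `converged` flag) and `summary` (min/median/max per parameter over
#'   converged folds).
#' @export
leave_one_out <- function(dataset, family = "constant",
                          covariate_terms = character(0), by = c("study", "arm"),
                          cov_refs = NULL, ...) {
  by <- match.arg(by)
  stopifnot(inherits(dataset, "mbma_dataset"))
  units <- unique(if (by == "study") dataset$arms$study_id else dataset$arms$arm_id)
  if (length(units) < 3) stop("leave-one-out needs at least 3 ", by, " units")
  if (is.null(cov_refs) && length(covariate_terms)) {
    cov_refs <- vapply(covariate_terms, function(nm) {
      stats::median(dataset$arms[[nm]])
    }, numeric(1))
  }
  rows <- list()
  for (u in units) {
    keep <- if (by == "study") dataset$arms$study_id != u else dataset$arms$arm_id != u
    sub_arms <- dataset$arms[keep, , drop = FALSE]
    sub_cur <- dataset$curves[dataset$curves$arm_id %in% sub_arms$arm_id, , drop = FALSE]
    sub <- mbma_dataset(sub_arms, sub_cur, monotone = "ignore")
    f <- tryCatch(fit_model(sub, family = family,
                            covariate_terms = covariate_terms,
                            cov_refs = cov_refs, ...),
                  error = function(e) NULL)
    if (is.null(f) || is.null(f$estimates)) {
      warning("fold dropping '", u, "' did not converge")
      rows[[u]] <- data.frame(held_out = u, converged = FALSE)
    } else {
      rows[[u]] <- cbind(data.frame(held_out = u,
                                    converged = isTRUE(f$converged)),
                         as.data.frame(as.list(f$estimates)))
    }
  }
  folds <- do.call(rbind, lapply(rows, function(d) {
    # pad missing estimate columns for failed folds
    all_cols <- unique(unlist(lapply(rows, names)))
    for (cc in setdiff(all_cols, names(d))) d[[cc]] <- NA_real_
    d[all_cols]
  }))
  rownames(folds) <- NULL
  est_cols <- setdiff(names(folds), c("held_out", "converged"))
  ok <- folds$converged %in% TRUE
  summ <- do.call(rbind, lapply(est_cols, function(cc) {
    v <- folds[[cc]][ok]
    data.frame(parameter = cc, min = min(v), median = stats::median(v),
               max = max(v))
  }))
  list(folds = folds, summary = summ)
}
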