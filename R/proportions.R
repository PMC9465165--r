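#' Random-effects meta-analysis of single-arm proportions
#'
#' Pools per-arm event proportions with inverse-variance weights and a
#' DerSimonian-Laird between-arm variance (REML or fixed-effect selectable).
#' The default logit transform keeps back-transformed confidence intervals
#' inside \[0, 100\]; raw-proportion and Freeman-Tukey double-arcsine
#' transforms are available. Arms with 0 or all events get a 0.5 continuity
#' correction under the logit transform, with a warning.
#'
#' @param events,total integer vectors of per-arm event and patient counts.
#' @param transform `"logit"` (default), `"raw"` or `"ft"` (Freeman-Tukey).
#' @param method `"DL"` (default), `"REML"` or `"FE"`.
#' @return list of class `pooled_proportion`: `pooled_pct`, `ci_lower`,
#'   `ci_upper` (percentages), `tau2` (transformed scale), `k`, `n_total`.
#' @export
pool_proportions <- function(events, total, transform = c("logit", "raw", "ft"),
                             method = c("DL", "REML", "FE")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  stopifnot(length(events) == length(total), length(events) >= 1,
            all(total >= 1), all(events >= 0), all(events <= total))
  measure <- switch(transform, logit = "PLO", raw = "PR", ft = "PFT")
  if (transform == "logit" && any(events == 0 | events == total)) {
    warning("boundary proportion(s): applying 0.5 continuity correction")
  }
  es <- metafor::escalc(measure = measure, xi = events, ni = total,
                        add = 1 / 2, to = "only0")
  if (length(events) == 1L) {
    est <- es$yi[1]; se <- sqrt(es$vi[1]); tau2 <- 0
  } else {
    rm <- metafor::rma(yi = es$yi, vi = es$vi,
                       method = if (method == "FE") "FE" else method)
    est <- as.numeric(rm$beta); se <- rm$se
    tau2 <- if (method == "FE") 0 else rm$tau2
  }
  ci <- est + c(-1.96, 1.96) * se
  back <- switch(transform,
    logit = function(z) stats::plogis(z),
    raw = function(z) pmin(pmax(z, 0), 1),
    ft = function(z) metafor::transf.ipft.hm(z, targs = list(ni = total)))
  structure(list(pooled_pct = 100 * back(est),
                 ci_lower = 100 * back(ci[1]), ci_upper = 100 * back(ci[2]),
                 tau2 = tau2, k = length(events), n_total = sum(total),
                 transform = transform, method = method),
            class = "pooled_proportion")
}

#' @export
print.pooled_proportion <- function(x, ...) {
  cat(sprintf("<pooled_proportion> %.1f%% (%.1f-%.1f), k=%d, n=%d, tau2=%.4g [%s/%s]\n",
              x$pooled_pct, x$ci_lower, x$ci_upper, x$k, x$n_total, x$tau2,
              x$transform, x$method))
  invisible(x)
}

#' Pooled response and toxicity report by endpoint and regimen
#'
#' Runs [pool_proportions()] for every endpoint-by-regimen cell with counts
#' in the dataset (objective response plus the six grade 3-4 adverse-event
#' endpoints). Cells with no counts are reported as absent (NA), not zero.
#'
#' @param dataset an `mbma_dataset` whose `counts` table is populated.
#' @param transform,method passed to [pool_proportions()].
#' @return data.frame (endpoint, regimen, k, n_total, pooled_pct, ci_lower,
#'   ci_upper, tau2, formatted) with one row per endpoint x regimen present
#'   in the arms table.
#' @export
endpoint_report <- function(dataset, transform = "logit", method = "DL") {
  stopifnot(inherits(dataset, "mbma_dataset"))
  if (is.null(dataset$counts)) stop("dataset has no counts table")
  cn <- dataset$counts
  reg_by_arm <- stats::setNames(dataset$arms$regimen, dataset$arms$arm_id)
  cn$regimen <- reg_by_arm[as.character(cn$arm_id)]
  regs <- intersect(REGIMENS, unique(dataset$arms$regimen))
  rows <- list()
  for (ep in ENDPOINTS) {
    for (rg in regs) {
      sel <- cn[cn$endpoint == ep & cn$regimen == rg, , drop = FALSE]
      if (!nrow(sel)) {
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = ep, regimen = rg, k = 0L, n_total = 0L,
          pooled_pct = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
          tau2 = NA_real_, formatted = "absent")
        next
      }
      p <- pool_proportions(sel$events, sel$total, transform, method)
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, regimen = rg, k = p$k, n_total = p$n_total,
        pooled_pct = p$pooled_pct, ci_lower = p$ci_lower,
        ci_upper = p$ci_upper, tau2 = p$tau2,
        formatted = sprintf("%.1f (%.1f-%.1f)", p$pooled_pct, p$ci_lower,
                            p$ci_upper))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
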