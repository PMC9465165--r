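#' Upper-tail chi-squared threshold
#'
#' Critical OFV drop for one covariate at significance level `alpha`:
#' the upper-`alpha` quantile of the chi-squared distribution with `df`
#' degrees of freedom (3.84 at alpha = 0.05, 6.63 at alpha = 0.01, df = 1).
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return quantile value.
#' @export
chi2_threshold <- function(alpha, df = 1) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(df) || df < 1) stop("df must be >= 1")
  stats::qchisq(1 - alpha, df)
}

# canonical candidate ordering used as tie-break: demographics first, then
# performance status, stage, histology
CANDIDATE_ORDER <- c("age_median", "male_pct", "ps2_pct", "stage4_pct",
                     "scc_pct", "adc_pct", "lcc_pct")

#' Stepwise covariate selection on OFV drops
#'
#' Forward inclusion followed by backward deletion on the marginal objective
#' function value. The forward phase repeatedly refits the model with each
#' remaining candidate added and accepts the candidate with the largest OFV
#' drop, provided the drop is at least `forward_threshold`; ties are broken
#' by the fixed candidate order (age, sex, PS, stage, histology). The
#' backward phase refits with each retained term deleted and removes the term
#' whose deletion raises the OFV least, as long as that rise is below
#' `backward_threshold`, until stable. Centring constants are frozen at the
#' full-dataset medians when selection starts and stored in the returned
#' model.
#'
#' @param dataset an `mbma_dataset`.
#' @param candidates candidate covariate columns (default: all seven).
#' @param forward_threshold minimum OFV drop for inclusion (default 3.84,
#'   chi-squared alpha = 0.05, df = 1).
#' @param backward_threshold minimum OFV rise for retention (default 6.63,
#'   chi-squared alpha = 0.01, df = 1).
#' @param family hazard family.
#' @param ... further arguments to [fit_model()].
#' @return list with `fit` (final refitted `mbma_fit`) and `trace`
#'   (data.frame: step, direction, covariate, delta_ofv, accepted, note).
#' @export
stepwise_select <- function(dataset, candidates = CANDIDATE_ORDER,
                            forward_threshold = chi2_threshold(0.05, 1),
                            backward_threshold = chi2_threshold(0.01, 1),
                            family = "constant", ...) {
  stopifnot(all(candidates %in% names(dataset$arms)))
  candidates <- candidates[order(match(candidates, CANDIDATE_ORDER))]
  refs <- vapply(union(candidates, character(0)), function(nm) {
    stats::median(dataset$arms[[nm]])
  }, numeric(1))

  trace <- data.frame(step = integer(0), direction = character(0),
                      covariate = character(0), delta_ofv = numeric(0),
                      accepted = logical(0), note = character(0))
  add_trace <- function(step, dir, cov, dofv, acc, note = "") {
    trace[nrow(trace) + 1L, ] <<- list(step, dir, cov, dofv, acc, note)
  }

  refit <- function(terms) {
    tryCatch(fit_model(dataset, family = family, covariate_terms = terms,
                       cov_refs = refs, ...),
             error = function(e) structure(list(converged = FALSE,
                                                message = conditionMessage(e)),
                                           class = "mbma_fit"))
  }

  current_terms <- character(0)
  current <- refit(current_terms)
  if (is.null(current$ofv)) stop("base model failed to fit: ", current$message)
  step <- 0L

  # forward inclusion
  repeat {
    remaining <- setdiff(candidates, current_terms)
    if (!length(remaining)) break
    step <- step + 1L
    drops <- rep(NA_real_, length(remaining))
    names(drops) <- remaining
    cand_fits <- list()
    for (cand in remaining) {
      f <- refit(c(current_terms, cand))
      if (is.null(f$ofv) || !is.finite(f$ofv)) {
        add_trace(step, "forward", cand, NA_real_, FALSE, "refit failed; skipped")
        next
      }
      drops[cand] <- current$ofv - f$ofv
      cand_fits[[cand]] <- f
    }
    if (all(is.na(drops))) break
    best <- names(drops)[which.max(drops)]  # first max wins -> fixed order
    for (cand in remaining) {
      if (is.na(drops[cand])) next
      acc <- cand == best && drops[cand] >= forward_threshold
      add_trace(step, "forward", cand, drops[cand], acc)
    }
    if (is.na(drops[best]) || drops[best] < forward_threshold) break
    current_terms <- c(current_terms, best)
    current <- cand_fits[[best]]
  }

  # backward deletion
  repeat {
    if (!length(current_terms)) break
    step <- step + 1L
    rises <- rep(NA_real_, length(current_terms))
    names(rises) <- current_terms
    del_fits <- list()
    for (term in current_terms) {
      f <- refit(setdiff(current_terms, term))
      if (is.null(f$ofv) || !is.finite(f$ofv)) {
        add_trace(step, "backward", term, NA_real_, FALSE, "refit failed; skipped")
        next
      }
      rises[term] <- f$ofv - current$ofv
      del_fits[[term]] <- f
    }
    if (all(is.na(rises))) break
    weakest <- names(rises)[which.min(rises)]
    drop_it <- !is.na(rises[weakest]) && rises[weakest] < backward_threshold
    for (term in current_terms) {
      if (is.na(rises[term])) next
      add_trace(step, "backward", term, rises[term], term == weakest && drop_it)
    }
    if (!drop_it) break
    current_terms <- setdiff(current_terms, weakest)
    current <- del_fits[[weakest]]
  }

  list(fit = current, trace = trace, final_terms = current_terms)
}

#' Write a selection trace as CSV
#'
#' @param selection result of [stepwise_select()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_selection_trace <- function(selection, path) {
  utils::write.csv(selection$trace, path, row.names = FALSE)
  invisible(path)
}
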