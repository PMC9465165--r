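#' @keywords internal
REGIMENS <- c("GV", "GD", "G")

#' @keywords internal
ARM_COLS <- c("study_id", "arm_id", "regimen", "n", "age_median", "male_pct",
              "ps2_pct", "stage4_pct", "scc_pct", "adc_pct", "lcc_pct")

#' @keywords internal
AE_ENDPOINTS <- c("anemia", "leukopenia", "neutropenia", "thrombocytopenia",
                  "nausea_vomiting", "fatigue_asthenia")

#' @keywords internal
ENDPOINTS <- c("ORR", AE_ENDPOINTS)

PCT_COLS <- c("male_pct", "ps2_pct", "stage4_pct", "scc_pct", "adc_pct",
              "lcc_pct")

#' Assemble and validate a study-level dataset
#'
#' A dataset holds one row per treatment arm (design covariates and sample
#' size), the aggregate overall-survival curve points per arm (time in months,
#' survival probability, optional standard error), and optionally per-arm
#' event counts for response/toxicity endpoints.
#'
#' Non-monotone curves (a survival value exceeding the previous one) are a
#' digitization artifact when curves come from published figures, but they
#' also arise legitimately under the additive residual-error model, so they
#' are never rejected. `monotone = "warn"` (default) reports them;
#' `"repair"` additionally applies isotonic clipping (each point capped at
#' the previous survival value), appropriate for digitized input;
#' `"ignore"` accepts them silently, appropriate for model-simulated data.
#'
#' @param arms data.frame with columns study_id, arm_id, regimen, n,
#'   age_median, male_pct, ps2_pct, stage4_pct, scc_pct, adc_pct, lcc_pct.
#' @param curves data.frame with columns arm_id, time_months, survival, se
#'   (se may be NA).
#' @param counts optional data.frame with columns arm_id, endpoint, events,
#'   total.
#' @param monotone handling of non-monotone survival within an arm: `"warn"`,
#'   `"repair"` or `"ignore"`.
#' @return an object of class `mbma_dataset`.
#' @export
mbma_dataset <- function(arms, curves, counts = NULL,
                         monotone = c("warn", "repair", "ignore")) {
  monotone <- match.arg(monotone)
  arms <- as.data.frame(arms)
  curves <- as.data.frame(curves)
  missing_cols <- setdiff(ARM_COLS, names(arms))
  if (length(missing_cols)) {
    stop("arms table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(arms$arm_id)) stop("duplicate arm_id in arms table")
  bad_reg <- setdiff(unique(arms$regimen), REGIMENS)
  if (length(bad_reg)) {
    stop("unknown regimen code(s): ", paste(bad_reg, collapse = ", "),
         " (expected GV, GD or G)")
  }
  num_cols <- setdiff(ARM_COLS, c("study_id", "arm_id", "regimen"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(arms[[cc]]))
    if (anyNA(v)) stop("non-numeric value in arms column '", cc, "'")
    arms[[cc]] <- v
  }
  if (any(arms$n < 1)) stop("arm sample size n must be >= 1")
  for (cc in PCT_COLS) {
    if (any(arms[[cc]] < 0 | arms[[cc]] > 100)) {
      stop("percentage column '", cc, "' outside [0, 100]")
    }
  }

  missing_cols <- setdiff(c("arm_id", "time_months", "survival"), names(curves))
  if (length(missing_cols)) {
    stop("curves table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(curves$se)) curves$se <- NA_real_
  for (cc in c("time_months", "survival", "se")) {
    v <- suppressWarnings(as.numeric(curves[[cc]]))
    if (anyNA(v) && cc != "se") {
      stop("non-numeric value in curves column '", cc, "'")
    }
    curves[[cc]] <- v
  }
  orphan <- setdiff(unique(curves$arm_id), arms$arm_id)
  if (length(orphan)) {
    stop("curve rows reference unknown arm_id(s): ", paste(orphan, collapse = ", "))
  }
  bad <- which(curves$survival < 0 | curves$survival > 1)
  if (length(bad)) {
    stop("survival outside [0, 1] in curves row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(curves$time_months < 0)) stop("negative time in curves table")
  if (any(!is.na(curves$se) & curves$se <= 0)) {
    stop("provided se values must be positive")
  }

  # per arm: sort by time, require strictly increasing times, handle monotonicity
  pieces <- split(curves, curves$arm_id)
  n_violate <- 0L
  pieces <- lapply(pieces, function(d) {
    d <- d[order(d$time_months), , drop = FALSE]
    if (anyDuplicated(d$time_months)) {
      stop("duplicate observation times within arm '", d$arm_id[1], "'")
    }
    clipped <- cummin(d$survival)
    n_violate <<- n_violate + sum(clipped < d$survival)
    if (monotone == "repair") d$survival <- clipped
    d
  })
  if (n_violate > 0 && monotone != "ignore") {
    warning(sprintf("%d non-monotone survival point(s) within arms%s",
                    n_violate,
                    if (monotone == "repair") "; repaired by isotonic clipping" else ""))
  }
  keep <- as.character(arms$arm_id[arms$arm_id %in% names(pieces)])
  curves <- do.call(rbind, pieces[keep])
  rownames(curves) <- NULL

  if (!is.null(counts)) {
    counts <- as.data.frame(counts)
    missing_cols <- setdiff(c("arm_id", "endpoint", "events", "total"), names(counts))
    if (length(missing_cols)) {
      stop("counts table is missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    orphan <- setdiff(unique(counts$arm_id), arms$arm_id)
    if (length(orphan)) {
      stop("count rows reference unknown arm_id(s): ", paste(orphan, collapse = ", "))
    }
    bad_ep <- setdiff(unique(counts$endpoint), ENDPOINTS)
    if (length(bad_ep)) {
      stop("unknown endpoint(s): ", paste(bad_ep, collapse = ", "))
    }
    counts$events <- as.numeric(counts$events)
    counts$total <- as.numeric(counts$total)
    if (any(counts$total < 1) || any(counts$events < 0) ||
        any(counts$events > counts$total)) {
      stop("counts must satisfy 0 <= events <= total, total >= 1")
    }
  }

  structure(list(arms = arms, curves = curves, counts = counts),
            class = "mbma_dataset")
}

#' @export
print.mbma_dataset <- function(x, ...) {
  cat(sprintf("<mbma_dataset> %d studies / %d arms / %d curve points",
              length(unique(x$arms$study_id)), nrow(x$arms), nrow(x$curves)))
  if (!is.null(x$counts)) cat(sprintf(" / %d count rows", nrow(x$counts)))
  cat("\n")
  invisible(x)
}

#' Read a dataset from CSV tables
#'
#' Reads the arm, curve and (optionally) count tables in the documented CSV
#' dialect and returns a validated dataset. Column layout:
#' arms `r paste(ARM_COLS, collapse = ", ")`; curves arm_id, time_months,
#' survival, se (se may be empty); counts arm_id, endpoint, events, total.
#'
#' @param arm_path,curve_path,counts_path CSV file paths; `counts_path` is
#'   optional.
#' @param monotone passed to [mbma_dataset()]; use `"repair"` for digitized
#'   curves and `"ignore"` for model-simulated exports.
#' @return an `mbma_dataset`.
#' @export
read_dataset <- function(arm_path, curve_path, counts_path = NULL,
                         monotone = "warn") {
  read1 <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  arms <- read1(arm_path)
  curves <- read1(curve_path)
  counts <- if (!is.null(counts_path)) read1(counts_path) else NULL
  mbma_dataset(arms, curves, counts, monotone = monotone)
}

#' Write a dataset to CSV tables
#'
#' Inverse of [read_dataset()]: `read_dataset` after `write_dataset` returns a
#' dataset equal field-for-field to the original.
#'
#' @param dataset an `mbma_dataset`.
#' @param arm_path,curve_path,counts_path output CSV paths; counts are written
#'   only when present and a path is given.
#' @return invisibly, the dataset.
#' @export
write_dataset <- function(dataset, arm_path, curve_path, counts_path = NULL) {
  stopifnot(inherits(dataset, "mbma_dataset"))
  utils::write.csv(dataset$arms, arm_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$curves, curve_path, row.names = FALSE, quote = FALSE)
  if (!is.null(counts_path) && !is.null(dataset$counts)) {
    utils::write.csv(dataset$counts, counts_path, row.names = FALSE, quote = FALSE)
  }
  invisible(dataset)
}

#' Resolve standard errors of survival observations
#'
#' Every curve point needs a finite positive standard error because the
#' residual model weights each observation by it. Reported SEs are kept as
#' authoritative; missing ones are filled with the binomial approximation
#' \eqn{\sqrt{S(1-S)/n}} using the arm's sample size, floored at `se_floor`
#' so boundary points (S = 0 or 1) do not receive infinite weight.
#' Idempotent.
#'
#' @param dataset an `mbma_dataset`.
#' @param se_floor minimum standard error (default 0.005).
#' @return the dataset with all curve SEs resolved.
#' @export
resolve_se <- function(dataset, se_floor = 0.005) {
  stopifnot(inherits(dataset, "mbma_dataset"))
  cur <- dataset$curves
  n_by_arm <- stats::setNames(dataset$arms$n, dataset$arms$arm_id)
  need <- is.na(cur$se)
  if (any(need)) {
    n <- n_by_arm[as.character(cur$arm_id[need])]
    if (anyNA(n)) stop("cannot resolve se: arm sample size missing")
    s <- cur$survival[need]
    cur$se[need] <- pmax(sqrt(s * (1 - s) / n), se_floor)
  }
  dataset$curves <- cur
  dataset
}
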