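#!/usr/bin/env Rscript
# Stage 4: evaluate the final model — goodness of fit, visual predictive
# check (overall and per regimen), and leave-one-out (by study) stability.

suppressPackageStartupMessages(library(survmbma))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args)) args[1] else 20220830)

ds <- read_dataset("results/data/arms.csv", "results/data/curves.csv",
                   "results/data/counts.csv", monotone = "ignore")
fm <- jsonlite::read_json("results/final_model.json", simplifyVector = TRUE)
fit <- fit_model(ds, family = fm$family, covariate_terms = fm$terms)

gof <- goodness_of_fit(fit, ds)
write.csv(gof, "results/goodness_of_fit.csv", row.names = FALSE)
cat(sprintf("weighted residuals: mean %.3f, sd %.3f (n = %d)\n",
            mean(gof$weighted_residual), sd(gof$weighted_residual),
            nrow(gof)))

vpc <- visual_predictive_check(fit, ds, n_sim = 1000, seed = seed)
write.csv(vpc$table, "results/vpc.csv", row.names = FALSE)
cat(sprintf("VPC: %.1f%% of observed points inside the 95%% band\n",
            100 * vpc$coverage))
for (rg in unique(vpc$table$regimen)) {
  sub <- vpc$table[vpc$table$regimen == rg, ]
  cat(sprintf("  %s: coverage %.3f over %d points\n", rg, mean(sub$inside),
              nrow(sub)))
}

# VPC panels, one per regimen plus all arms pooled
grDevices::png("results/vpc.png", width = 1600, height = 1200, res = 150)
graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
panels <- c(as.list(unique(vpc$table$regimen)), list(NULL))
for (rg in panels) {
  d <- if (is.null(rg)) vpc$table else vpc$table[vpc$table$regimen == rg, ]
  d <- d[order(d$time_months), ]
  plot(d$time_months, pmin(pmax(d$observed, 0), 1), cex = 0.3 + d$n / 200,
       pch = 16, col = "grey30", xlab = "months", ylab = "overall survival",
       main = if (is.null(rg)) "all regimens" else rg, ylim = c(0, 1))
  ot <- sort(unique(d$time_months))
  for (col in c("band_lower", "predicted_median", "band_upper")) {
    m <- vapply(ot, function(tt) median(d[[col]][d$time_months == tt]),
                numeric(1))
    lines(ot, pmin(pmax(m, 0), 1), lty = if (col == "predicted_median") 2 else 1,
          col = "grey60")
  }
}
grDevices::dev.off()

loo <- leave_one_out(ds, family = fm$family, covariate_terms = fm$terms)
write.csv(loo$folds, "results/loo_folds.csv", row.names = FALSE)
write.csv(loo$summary, "results/loo_summary.csv", row.names = FALSE)
cat("leave-one-out stability (per-parameter min / median / max):\n")
print(loo$summary)
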