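#!/usr/bin/env Rscript
# Stage 6: single-arm random-effects meta-analysis of the objective response
# rate and grade 3-4 adverse-event incidences, by regimen (logit transform,
# DerSimonian-Laird heterogeneity).

suppressPackageStartupMessages(library(survmbma))

ds <- read_dataset("results/data/arms.csv", "results/data/curves.csv",
                   "results/data/counts.csv", monotone = "ignore")
rep <- endpoint_report(ds)
write.csv(rep, "results/proportion_meta.csv", row.names = FALSE)

cat("pooled percentages (95% CI) by endpoint and regimen:\n")
wide <- reshape(rep[, c("endpoint", "regimen", "formatted")],
                idvar = "endpoint", timevar = "regimen", direction = "wide")
names(wide) <- sub("formatted\\.", "", names(wide))
print(wide, row.names = FALSE)
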