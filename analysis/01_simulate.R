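#!/usr/bin/env Rscript
# Stage 1: generate the study-level dataset the rest of the workflow analyses.
#
# The generator reproduces the structure of the literature base the analysis
# emulates: 17 studies / 20 arms (6 GV, 6 GD, 8 G), per-arm sample sizes of
# 19-215 patients, regimen-confounded age and PS2 distributions, monthly
# overall-survival observations to a per-arm horizon of 12-36 months, and
# per-arm response/toxicity counts. Generating truth: constant hazard
# 0.098/month, age coefficient 0.017 (ref 72.5 y), PS2 coefficient 0.004
# (ref 14%), inter-study SD 0.146, residual scale 0.822.

suppressPackageStartupMessages(library(survmbma))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args)) args[1] else 20220829)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

g <- generate_survival_dataset(generator_config(), seed = seed)
counts <- generate_count_data(g$dataset$arms, seed = seed + 1)
ds <- mbma_dataset(g$dataset$arms, g$dataset$curves, counts,
                   monotone = "ignore")
write_dataset(ds, "results/data/arms.csv", "results/data/curves.csv",
              "results/data/counts.csv")
jsonlite::write_json(
  list(seed = seed, eta = as.list(g$truth$eta),
       params = list(beta0 = 0.098, theta_age = 0.017, theta_ps2 = 0.004,
                     omega = 0.146, sigma_eps = 0.822)),
  "results/data/truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("wrote %d arms, %d curve points, %d count rows (seed %d)\n",
            nrow(ds$arms), nrow(ds$curves), nrow(ds$counts), seed))
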