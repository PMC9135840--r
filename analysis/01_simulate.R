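#!/usr/bin/env Rscript

# Step 1 — generate the synthetic study population.
#
# Simulates a hospital-network extract of 2,000 patients: DAA users spread
# over the ten prescription patterns (shares proportional to the published
# per-pattern cohort sizes), a 20% non-user background, kidney-function
# tests roughly every three weeks, and injected exclusion-criterion
# carriers. Writes the five raw tables plus the ground-truth table.

suppressPackageStartupMessages(library(renaldaa))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cfg <- simulation_config(n_patients = 2000, seed = seed)
sim <- simulate_dataset(cfg)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
paths <- write_dataset(sim$dataset, "results/data")
readr::write_csv(sim$truth, "results/data/ground_truth.csv")

cat("simulated", nrow(sim$dataset$patients), "patients ->",
    paste(basename(paths), collapse = ", "), "+ ground_truth.csv\n")
cat("  users:", sum(sim$truth$role == "user"),
    " eligible by construction:", sum(sim$truth$eligible), "\n")
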