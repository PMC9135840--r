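#!/usr/bin/env Rscript

# Step 2 — new-user cohort construction with the six exclusion criteria.
#
# Reads the simulated tables written by 01_simulate.R, identifies new DAA
# users (first prescription date = t0, at least 90 days of prior records),
# applies the exclusion criteria in flowchart order with duplicated
# counting, classifies the survivors into prescription patterns, and
# writes the attrition flowchart and the analyzable cohort.

suppressPackageStartupMessages(library(renaldaa))

ds <- read_dataset("results/data")
nu <- find_new_users(ds)
ex <- apply_exclusions(nu, ds)

print(ex$report)
readr::write_csv(as.data.frame(ex$report), "results/attrition.csv")
readr::write_csv(ex$cohort, "results/cohort.csv")
cat("cohort of", nrow(ex$cohort), "patients written to results/cohort.csv\n")
print(table(ex$cohort$pattern))
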