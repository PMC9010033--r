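#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic longitudinal cohort.
#
# Emits a 100-patient two-site cohort with known ground truth under
# data/cohort/ and a copy of the ground truth under results/. All later
# stages read only the written files, so the pipeline exercises the same
# interchange formats a real study export would use.

library(coalesceR)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

dir.create("results", showWarnings = FALSE)
config <- sim_config(n_patients = 100, seed = seed)
cohort <- simulate_cohort(config)

paths <- write_cohort(cohort, "data/cohort")
cat("wrote", length(paths), "files to data/cohort\n")
cat(sprintf("ground truth: %d/%d patients coalesce (median onset day %d)\n",
            sum(cohort$truth$coalesced), nrow(cohort$truth),
            as.integer(stats::median(cohort$truth$onset_day, na.rm = TRUE))))
write.table(cohort$truth, "results/ground_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
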