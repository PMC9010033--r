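#!/usr/bin/env Rscript
# Stage 6 — coalescence and infectious outcomes.
#
# Pearson chi-squared tests and Woolf odds ratios for infection before
# neutrophil recovery and in the 90 days after, by coalescence status.

library(coalesceR)

data <- read_cohort("data/cohort")
calls <- read.delim("results/coalescence_calls.tsv")
class(calls) <- c("coalescence_calls", "data.frame")

assoc <- coalescence_outcome_association(calls, data$outcomes)
print(assoc, digits = 3)

dir.create("results", showWarnings = FALSE)
write.table(assoc, "results/infection_association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
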