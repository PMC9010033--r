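#!/usr/bin/env Rscript
# Stage 4 — diversity trajectories by coalescence status.
#
# Random-intercept linear mixed models of oral and stool Shannon diversity
# on days since chemotherapy start, coalescence status and their
# interaction, plus the repeated-measures site-effect tests for typically
# oral genera in coalesced patients.

library(coalesceR)

data <- read_cohort("data/cohort")
calls <- read.delim("results/coalescence_calls.tsv")

alpha <- alpha_diversity(data$table)
alpha$coalesced <- calls$coalesced[match(alpha$patient_id, calls$patient_id)]

fits <- list()
for (s in c("oral", "stool")) {
  cat("\n==", s, "Shannon diversity ==\n")
  fit <- fit_lmm(alpha[alpha$site == s, ], "shannon",
                 c("day", "coalesced", "day:coalesced"))
  print(fit)
  cf <- fit$coefficients
  cf$site <- s
  fits[[s]] <- cf
}

oral_genera <- c("Streptococcus", "Stenotrophomonas", "Veillonella",
                 "Neisseria", "Actinomyces")
calls_cls <- calls
class(calls_cls) <- c("coalescence_calls", "data.frame")
records <- oral_taxa_site_comparison(data$table, data$taxonomy, oral_genera,
                                     calls_cls)
site_tests <- site_effect_tests(records, coalesced_only = TRUE)
cat("\nsite effect (stool - oral) per genus in coalesced patients:\n")
print(site_tests, digits = 3)

dir.create("results", showWarnings = FALSE)
write.table(do.call(rbind, fits), "results/lmm_shannon.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(site_tests, "results/site_effects.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
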