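#!/usr/bin/env Rscript
# Stage 2 — pooled community structure.
#
# PCoA of the Bray-Curtis dissimilarities over all samples, PERMANOVA of
# body site, per-group 95% confidence-ellipse membership (how many samples
# sit in both sites' ellipses), and average-linkage clustering of the
# distance matrix into three groups. Writes ordination coordinates,
# membership flags and the PERMANOVA summary under results/.

library(coalesceR)

data <- read_cohort("data/cohort")
validate_cohort(data$table, data$tree, data$taxonomy, data$exposures,
                data$outcomes)

d_bc <- bray_curtis(data$table)
ord <- pcoa(d_bc, n_axes = 2)
print(ord)

pv <- permanova(d_bc, data$table$samples$site, n_permutations = 999, seed = 1)
print(pv)

memb <- confidence_ellipse_overlap(ord, data$table$samples$site)
cat(sprintf("%.1f%% of samples fall inside both sites' 95%% ellipses\n",
            100 * mean(memb$in_both)))

clusters <- hierarchical_clusters(d_bc, k = 3)
mix <- table(clusters, data$table$samples$site)
cat("cluster x site composition:\n")
print(mix)

dir.create("results", showWarnings = FALSE)
write.table(cbind(sample_id = rownames(ord$coordinates), ord$coordinates,
                  cluster = clusters),
            "results/ordination.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(memb, "results/ellipse_membership.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(pseudo_F = pv$pseudo_F, r_squared = pv$r_squared,
                       p_value = pv$p_value, n_permutations = pv$n_permutations),
            "results/permanova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
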