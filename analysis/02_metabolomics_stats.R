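#!/usr/bin/env Rscript

# Stage 2: post-quantification metabolomics statistics.
#
# PQN-normalizes the simulated concentration table, screens every
# metabolite with uncorrected Mann-Whitney tests in the three group
# comparisons, and summarizes the group structure with PCA. The implanted
# shift from stage 1 should surface in the disease-vs-wildtype screen.

library(metabonet)

tab <- read_metabolite_table("results/data/metabolites.tsv")
truth <- jsonlite::read_json("results/data/ground_truth.json")
dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)

norm <- pqn_normalize(tab)
write_metabolite_table(norm, "results/stats/metabolites_pqn.tsv")

comparisons <- list(c("disease", "wildtype"),
                    c("disease_treated", "wildtype"),
                    c("disease_treated", "disease"))
univ <- do.call(rbind, lapply(comparisons, function(cmp) {
  univariate_screen(norm, cmp)
}))
utils::write.table(univ, "results/stats/univariate.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

hits <- univ[univ$significant, c("metabolite", "comparison", "p", "log2fc")]
message("significant metabolite tests (p < 0.05, uncorrected): ", nrow(hits))
print(hits, row.names = FALSE)
implanted <- unlist(truth$shifted)
found <- implanted %in% hits$metabolite[hits$comparison == "disease_vs_wildtype"]
message("implanted shift ", paste(implanted, collapse = ", "),
        if (all(found)) " recovered" else " NOT recovered",
        " in disease vs wildtype")

pca <- pca_scores(norm, k = 2)
utils::write.table(
  data.frame(sample = rownames(pca$scores), group = norm$group, pca$scores),
  "results/stats/pca_scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("PCA: first two components cover %.2f%% of the variance",
                pca$cumulative2))
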