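#!/usr/bin/env Rscript

# Stage 3: differential metabolite-metabolite correlation patterns.
#
# Computes per-group Pearson matrices on the normalized table, keeps only
# pairs significant in both groups of a comparison, and classifies the two
# treatment-relevant pattern classes: correlations that flip sign under
# treatment (and are absent from the wildtype-disease comparison), and
# disease-reversed correlations that the treatment corrects back toward the
# wildtype sign. At n = 10 per group the implanted pairs are not guaranteed
# to reach dual significance; the stage reports what it finds.

library(metabonet)

norm <- read_metabolite_table("results/stats/metabolites_pqn.tsv")
truth <- jsonlite::read_json("results/data/ground_truth.json")
dir.create("results/patterns", showWarnings = FALSE, recursive = TRUE)

mats <- groupwise_pearson(norm)
for (g in names(mats)) {
  idx <- which(upper.tri(mats[[g]]$r), arr.ind = TRUE)
  long <- data.frame(
    met_a = colnames(mats[[g]]$r)[idx[, 1]],
    met_b = colnames(mats[[g]]$r)[idx[, 2]],
    group = g, n = mats[[g]]$n,
    r = mats[[g]]$r[idx], p = mats[[g]]$p[idx])
  utils::write.table(long, sprintf("results/patterns/correlations_%s.tsv", g),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

opp <- find_opposite_treatment_pairs(mats)
corr <- find_corrected_pairs(mats)
message("opposite-under-treatment pairs: ", nrow(opp))
if (nrow(opp)) print(opp[, c("met_a", "met_b", "r_disease", "r_disease_treated")],
                     row.names = FALSE)
message("corrected-toward-wildtype pairs: ", nrow(corr))
if (nrow(corr)) print(corr[, c("met_a", "met_b", "r_wildtype", "r_disease",
                               "r_disease_treated")], row.names = FALSE)

implanted <- vapply(truth$pattern_pairs, function(p) p$pair, "")
found <- implanted %in% c(pair_key(opp$met_a, opp$met_b),
                          pair_key(corr$met_a, corr$met_b))
message("implanted pairs detected at this sample size: ",
        sum(found), "/", length(implanted))

out <- rbind(
  if (nrow(opp)) opp[, c("met_a", "met_b", "class")],
  if (nrow(corr)) corr[, c("met_a", "met_b", "class")])
if (is.null(out)) {
  out <- data.frame(met_a = character(), met_b = character(),
                    class = character())
}
utils::write.table(out, "results/patterns/pattern_pairs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
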