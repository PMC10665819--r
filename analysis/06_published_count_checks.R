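#!/usr/bin/env Rscript

# Stage 6: checks against published summary counts.
#
# The per-animal measurements behind the published tissue-metabolite tables
# are not public, so these checks run on (i) the transcribed summary tables
# (means, SDs and significance marks) and (ii) a synthetic DE benchmark
# constructed to the published marginal counts, exercising the package's
# selection rules at the published sizes.

library(metabonet)
dir.create("results/published", showWarnings = FALSE, recursive = TRUE)

short <- read_metabolite_summary(system.file(
  "extdata", "metabolite_summary_short_treatment.tsv", package = "metabonet"))
long <- read_metabolite_summary(system.file(
  "extdata", "metabolite_summary_long_treatment.tsv", package = "metabonet"))

counts <- data.frame(
  table = c("short", "short", "long", "long"),
  comparison = rep(c("disease_vs_wildtype", "treated_vs_disease"), 2),
  n_metabolites = c(nrow(short), nrow(short), nrow(long), nrow(long)),
  n_significant = c(
    count_significant_marks(short, "disease_vs_wildtype"),
    count_significant_marks(short, "treated_vs_disease"),
    count_significant_marks(long, "disease_vs_wildtype"),
    count_significant_marks(long, "treated_vs_disease")))
print(counts, row.names = FALSE)
utils::write.table(counts, "results/published/summary_mark_counts.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

de <- make_de_benchmark(seed = 2026)
sel <- select_de_genes(de, fdr_cut = 0.05, lfc_cut = 0.5)
n_fdr <- sum(de$fdr < 0.05)
overlap <- 100 * sum(de$fdr < 0.05 & de$sig_disease_vs_wildtype) / n_fdr
message("FDR-significant genes: ", n_fdr, " (",
        sum(de$fdr < 0.05 & de$log2fc > 0), " up, ",
        sum(de$fdr < 0.05 & de$log2fc < 0), " down)")
message("combined union selection: ",
        length(sel$up) + length(sel$down) + length(sel$zero), " genes (",
        length(sel$up), " up, ", length(sel$down), " down)")
message(sprintf("overlap with the wildtype comparison: %.1f%%", overlap))
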