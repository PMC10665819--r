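#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs.
#
# Builds a seeded toy stoichiometric model (cofactor couple, transporter,
# irreversible reaction, gene associations), a three-group metabolite
# concentration table with one implanted disease shift and two implanted
# correlation-pattern pairs, and a gene-level statistics table with one
# planted signal ratio. Everything downstream runs from the files written
# here; ground truth is saved alongside for the later stages to check
# against.

library(metabonet)

seed <- 2026
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

model <- make_toy_model(seed, n_core_metabolites = 10, n_reactions = 14)
write_model(model, file.path(out, "model.json"))
message("model: ", nrow(model$metabolites), " metabolites, ",
        length(model$reactions), " reactions; uniquely produced: ",
        paste(model$uniquely_produced, collapse = ", "))

measured_ids <- grep("^met\\d+_c$", model$metabolites$id, value = TRUE)
measured <- model$metabolites$name[match(measured_ids, model$metabolites$id)]

cfg <- synthetic_config(
  seed = seed, n_per_group = 10, metabolites = measured,
  metabolite_effects = stats::setNames(
    list(list(group = "disease", shift = 2)), measured[5]),
  latent_factors = list(
    list(metabolites = measured[c(1, 2)],
         loadings = list(wildtype = c(0, 0), disease = c(2, 2),
                         disease_treated = c(2, -2))),
    list(metabolites = measured[c(3, 4)],
         loadings = list(wildtype = c(2, 2), disease = c(2, -2),
                         disease_treated = c(2, 2)))))
sim <- simulate_metabolite_table(cfg)
write_metabolite_table(sim$table, file.path(out, "metabolites.tsv"))
message("metabolite table: ", nrow(sim$table), " samples x ",
        length(measured), " metabolites; shifted: ",
        paste(sim$truth$shifted_metabolites, collapse = ", "))

ratios <- suppressMessages(build_ratio_gene_map(model))
gs <- simulate_gene_stats(model, synthetic_config(
  seed = seed, metabolites = measured,
  signal_ratios = ratios$ratio[1], signal_beta_a = 0.1))
# a real differential-expression table is transcriptome-wide: pad the model
# genes with a uniform null background so the rank transform sees the same
# kind of pool it would on sequencing output
background <- local({
  set.seed(seed + 1)
  p <- runif(600)
  data.frame(gene = sprintf("bg%04d", seq_along(p)), p = p,
             log2fc = sample(c(-1, 1), length(p), TRUE) *
               abs(stats::qnorm(pmax(p, 1e-300) / 2)) / 3,
             fdr = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
})
gene_table <- rbind(gs$gene_stats, background)
utils::write.table(gene_table, file.path(out, "genes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("gene table: ", nrow(gene_table), " genes (",
        nrow(gs$gene_stats), " on the model); signal ratio: ",
        ratios$ratio[1], " (genes ",
        paste(gs$truth$signal_genes, collapse = ", "), ")")

truth <- list(seed = seed,
              shifted = sim$truth$shifted_metabolites,
              pattern_pairs = sim$truth$pattern_pairs,
              signal_ratio = ratios$ratio[1])
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE, force = TRUE)
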