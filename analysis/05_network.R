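#!/usr/bin/env Rscript

# Stage 5: assemble, filter and export the integrated metabolite network.
#
# Maps the measured metabolite names onto the model, finds all one- and
# two-step reaction paths between measured, bridge and reporter-selected
# metabolites (half-reaction decoupling, hub exclusion, zero-weight
# transporters), attaches the omics annotations, drops components with
# fewer than three significant members, and exports node-link JSON and
# GraphML payloads.

library(metabonet)

model <- load_model("results/data/model.json")
norm <- read_metabolite_table("results/stats/metabolites_pqn.tsv")
univ <- utils::read.delim("results/stats/univariate.tsv")
genes <- read_gene_stats("results/data/genes.tsv")
reporter_mets <- if (file.exists("results/reporter/reporter_metabolites.txt")) {
  readLines("results/reporter/reporter_metabolites.txt")
} else character()
dir.create("results/network", showWarnings = FALSE, recursive = TRUE)

mapped <- map_measured_metabolites(setdiff(names(norm), c("sample", "group")),
                                   model)
message("mapped ", nrow(mapped$mapping), " measured metabolites; unmatched: ",
        if (length(mapped$unmatched)) paste(mapped$unmatched, collapse = ", ")
        else "none")

sig_tab <- univ[univ$comparison == "disease_treated_vs_disease", ]
idx <- match(mapped$mapping$name, sig_tab$metabolite)
ann <- list(
  metabolites = data.frame(id = mapped$mapping$metabolite_id,
                           log2fc = sig_tab$log2fc[idx],
                           significant = sig_tab$significant[idx]),
  genes = data.frame(id = genes$gene, p = genes$p, fdr = genes$fdr,
                     log2fc = genes$log2fc))

net <- build_network(measured = mapped$mapping$metabolite_id,
                     bridges = character(), model = model,
                     reporter = reporter_mets, annotations = ann)
print(net)

sel <- select_de_genes(genes)
sig_nodes <- c(net$nodes$id[net$nodes$type == "metabolite" &
                              !is.na(net$nodes$significant) &
                              net$nodes$significant],
               intersect(net$nodes$id, c(sel$up, sel$down)))
filtered <- filter_subnetworks(net, significant = unique(sig_nodes))
message("after filtering (>= 3 significant nodes per component): ",
        nrow(filtered$nodes), " nodes, ", nrow(filtered$edges), " edges in ",
        length(unique(filtered$nodes$component)), " component(s)")

export_graph(net, "results/network/network_full.json")
export_graph(filtered, "results/network/network_filtered.json")
export_graph(filtered, "results/network/network_filtered.graphml",
             format = "graphml")
message("exports written under results/network/")
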