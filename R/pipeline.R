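#' Pipeline configuration
#'
#' Collects every input path (or in-memory object), threshold and seed of an
#' end-to-end run. Thresholds default to the analysis levels used
#' throughout: 0.05 for metabolite, correlation and reporter significance;
#' FDR < 0.05 and/or |log2FC| > 0.5 for gene selection; 100000 null draws
#' per reporter ratio.
#'
#' @param metabolite_table Path to a metabolite TSV, or a metabolite table
#'   data.frame.
#' @param gene_table Path to a gene statistics TSV, or a data.frame.
#' @param model Path to a model JSON file, or a `metabolic_model`.
#' @param out_dir Output directory (created if missing).
#' @param alpha_metabolite,alpha_correlation,alpha_reporter Significance
#'   levels, each in `(0, 1)`.
#' @param fdr_cut,lfc_cut Gene selection thresholds (positive).
#' @param n_sim Reporter null draws per ratio.
#' @param seed Integer seed for all randomness in the run.
#' @param bridges Character vector of bridge metabolite ids added to the
#'   network to prevent gaps in the classical pathways.
#' @param pqn_reference PQN reference policy (see [pqn_normalize()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(metabolite_table, gene_table, model, out_dir,
                            alpha_metabolite = 0.05, alpha_correlation = 0.05,
                            alpha_reporter = 0.05, fdr_cut = 0.05,
                            lfc_cut = 0.5, n_sim = 100000, seed = 1,
                            bridges = character(),
                            pqn_reference = "all-samples") {
  for (a in c(alpha_metabolite, alpha_correlation, alpha_reporter)) {
    if (a <= 0 || a >= 1) stop("alpha levels must lie in (0, 1)")
  }
  if (fdr_cut <= 0 || lfc_cut <= 0) stop("selection thresholds must be positive")
  structure(list(metabolite_table = metabolite_table, gene_table = gene_table,
                 model = model, out_dir = out_dir,
                 alpha_metabolite = alpha_metabolite,
                 alpha_correlation = alpha_correlation,
                 alpha_reporter = alpha_reporter,
                 fdr_cut = fdr_cut, lfc_cut = lfc_cut, n_sim = n_sim,
                 seed = seed, bridges = bridges,
                 pqn_reference = pqn_reference),
            class = "pipeline_config")
}

#' Run the full integration pipeline
#'
#' Executes, in order: PQN normalization, univariate Mann-Whitney screens of
#' the three group comparisons, PCA, per-group correlation pattern mining,
#' DE gene selection, the reporter-ratio analysis, constrained path-network
#' assembly (measured + bridge + reporter metabolites), subnetwork
#' filtering, and file export. Every stage's output is persisted under
#' `out_dir`; outputs are identical for identical config and seed. Any stage
#' error aborts with the stage name and the run report collected so far.
#'
#' @param cfg A [pipeline_config()].
#' @return A run report: list with per-stage record counts, warnings, the
#'   config echo and the seed, written additionally to
#'   `out_dir/run_report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg[setdiff(names(cfg), c("metabolite_table", "gene_table", "model"))],
                 stages = list(), warnings = character())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
  }
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        report$stages[[stage]] <- list(error = conditionMessage(e))
        jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                             auto_unbox = TRUE, pretty = TRUE, force = TRUE)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  out <- function(name) file.path(cfg$out_dir, name)

  # --- load inputs -----------------------------------------------------
  table <- run_stage("load", {
    if (is.character(cfg$metabolite_table)) read_metabolite_table(cfg$metabolite_table)
    else cfg$metabolite_table
  })
  genes <- if (is.character(cfg$gene_table)) read_gene_stats(cfg$gene_table) else cfg$gene_table
  model <- if (is.character(cfg$model)) load_model(cfg$model) else cfg$model
  note("load", samples = nrow(table),
       metabolites = ncol(metabolite_matrix(table)),
       genes = nrow(genes), reactions = length(model$reactions))

  # --- normalization ---------------------------------------------------
  norm <- run_stage("pqn", pqn_normalize(table, cfg$pqn_reference))
  write_metabolite_table(norm, out("metabolites_pqn.tsv"))
  note("pqn", samples = nrow(norm))

  # --- univariate screens ---------------------------------------------
  comparisons <- list(c("disease", "wildtype"),
                      c("disease_treated", "wildtype"),
                      c("disease_treated", "disease"))
  univ <- run_stage("univariate", do.call(rbind, lapply(
    comparisons, function(cmp) univariate_screen(norm, cmp, cfg$alpha_metabolite))))
  utils::write.table(univ, out("univariate.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("univariate", tests = nrow(univ), significant = sum(univ$significant))

  # --- PCA -------------------------------------------------------------
  pca <- run_stage("pca", pca_scores(norm, k = 2))
  utils::write.table(
    data.frame(sample = rownames(pca$scores), pca$scores),
    out("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  note("pca", cumulative2 = pca$cumulative2)

  # --- correlation patterns -------------------------------------------
  mats <- run_stage("correlations", groupwise_pearson(norm))
  opposite <- run_stage("patterns", find_opposite_treatment_pairs(mats, cfg$alpha_correlation))
  corrected <- find_corrected_pairs(mats, cfg$alpha_correlation)
  patterns <- merge_pattern_tables(opposite, corrected)
  utils::write.table(patterns, out("pattern_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("patterns", opposite = nrow(opposite), corrected = nrow(corrected))

  # --- DE gene selection ----------------------------------------------
  de <- run_stage("de_selection", select_de_genes(genes, cfg$fdr_cut, cfg$lfc_cut))
  note("de_selection", up = length(de$up), down = length(de$down),
       zero = length(de$zero))

  # --- reporter ratios -------------------------------------------------
  reporter <- run_stage("reporter", suppressMessages(
    reporter_analysis(model, genes, n_sim = cfg$n_sim, seed = cfg$seed,
                      alpha = cfg$alpha_reporter)))
  utils::write.table(reporter, out("reporter_ratios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  reporter_mets <- select_reporter_metabolites(reporter, cfg$alpha_reporter)
  note("reporter", ratios = nrow(reporter),
       significant = sum(reporter$significant),
       reporter_metabolites = length(reporter_mets))

  # --- network ---------------------------------------------------------
  net <- run_stage("network", {
    mapped <- map_measured_metabolites(colnames(metabolite_matrix(norm)), model)
    measured <- unique(mapped$mapping$metabolite_id)
    if (length(mapped$unmatched)) {
      report$warnings <<- c(report$warnings, paste0(
        "network: unmatched metabolite name(s): ",
        paste(mapped$unmatched, collapse = ", ")))
    }
    sig_tab <- univ[univ$comparison == "disease_treated_vs_disease", ]
    ann <- list(
      metabolites = data.frame(id = measured,
                               log2fc = sig_tab$log2fc[match(
                                 mapped$mapping$name[match(measured, mapped$mapping$metabolite_id)],
                                 sig_tab$metabolite)],
                               significant = sig_tab$significant[match(
                                 mapped$mapping$name[match(measured, mapped$mapping$metabolite_id)],
                                 sig_tab$metabolite)],
                               stringsAsFactors = FALSE),
      genes = data.frame(id = genes$gene, p = genes$p, fdr = genes$fdr,
                         log2fc = genes$log2fc, stringsAsFactors = FALSE))
    build_network(measured, bridges = cfg$bridges, model = model,
                  reporter = reporter_mets, annotations = ann)
  })
  sig_flag <- if ("significant" %in% names(net$nodes)) {
    isTRUE_vec(net$nodes$significant)
  } else {
    rep(FALSE, nrow(net$nodes))
  }
  sig_mets <- net$nodes$id[net$nodes$type == "metabolite" & sig_flag]
  sig_genes <- intersect(net$nodes$id, c(de$up, de$down))
  filtered <- run_stage("filter", filter_subnetworks(
    net, significant = c(sig_mets, sig_genes)))
  export_graph(net, out("network_full.json"))
  export_graph(filtered, out("network_filtered.json"))
  export_graph(filtered, out("network_filtered.graphml"), format = "graphml")
  note("network", nodes = nrow(net$nodes), edges = nrow(net$edges),
       filtered_nodes = nrow(filtered$nodes),
       filtered_edges = nrow(filtered$edges),
       significant_nodes = length(c(sig_mets, sig_genes)))

  report$seed <- cfg$seed
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(report)
}

# TRUE where x is TRUE, FALSE for FALSE/NA.
isTRUE_vec <- function(x) !is.na(x) & x

# Align the two pattern-pair tables on shared columns for one output file.
merge_pattern_tables <- function(opposite, corrected) {
  cols <- c("met_a", "met_b", "class",
            "r_wildtype", "p_wildtype", "r_disease", "p_disease",
            "r_disease_treated", "p_disease_treated")
  fix <- function(df) {
    for (cn in setdiff(cols, names(df))) df[[cn]] <- rep(NA_real_, nrow(df))
    df[, cols, drop = FALSE]
  }
  out <- rbind(fix(opposite), fix(corrected))
  rownames(out) <- NULL
  out
}
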