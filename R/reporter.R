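#' Three-step weight normalization for ratio-gene links
#'
#' Some metabolite ratios (e.g. currency couples) are touched by many
#' reactions while others are specific to a single enzyme, so raw gene counts
#' would bias the Fisher sum. The weights are computed in three steps:
#' every weight starts at one; each is divided by the number of genes
#' connected to its ratio; and finally each gene's weights are divided by
#' that gene's maximum weight over all its ratios, so every gene has maximum
#' weight exactly one somewhere.
#'
#' @param ratios A ratio-gene map as from [build_ratio_gene_map()] (columns
#'   `ratio`, `met_a`, `met_b`, list column `genes`, `n_genes`); every ratio
#'   must have at least one gene.
#' @return A long data.frame with columns `ratio`, `gene`, `weight`
#'   (in `(0, 1]`).
#' @export
compute_weights <- function(ratios) {
  if (!nrow(ratios)) {
    return(data.frame(ratio = character(), gene = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  if (any(ratios$n_genes < 1L)) stop("every ratio needs at least one gene")
  long <- do.call(rbind, lapply(seq_len(nrow(ratios)), function(i) {
    data.frame(ratio = ratios$ratio[i], gene = ratios$genes[[i]],
               weight = 1 / ratios$n_genes[i],  # steps 1 + 2
               stringsAsFactors = FALSE)
  }))
  gene_max <- tapply(long$weight, long$gene, max)
  long$weight <- as.numeric(long$weight / gene_max[long$gene])  # step 3
  long
}

#' Rank-based inverse uniform transform of p-values
#'
#' Replaces each p-value by `rank / (N + 1)` (ascending ranks, ties by
#' average rank), forcing an exactly uniform marginal over the observed set.
#' The output lies strictly inside `(0, 1)`, so log transforms are safe.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (non-empty).
#' @return Transformed values, same length and order as the input.
#' @examples
#' rank_inverse_uniform(c(0.01, 0.5, 0.9))  # 0.25 0.50 0.75
#' @export
rank_inverse_uniform <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  rank(p_values, ties.method = "average") / (length(p_values) + 1)
}

#' Weighted Fisher statistic for one metabolite ratio
#'
#' `X_i = -sum_j w_ij * ln(p_j)` over the genes connected to ratio `i`, where
#' `p_j` is the rank-transformed p-value of gene `j` and `w_ij` its
#' normalized weight. Larger X means more concentrated differential
#' expression among the enzymes flanking the ratio.
#'
#' @param weights Long weight table (rows of [compute_weights()] for one
#'   ratio: columns `gene`, `weight`).
#' @param transformed_p Named numeric vector of rank-transformed p-values,
#'   names are gene ids.
#' @return The statistic `X_i` (non-negative scalar).
#' @export
weighted_fisher <- function(weights, transformed_p) {
  missing <- setdiff(weights$gene, names(transformed_p))
  if (length(missing)) {
    stop("no transformed p-value for gene(s) ",
         paste(missing, collapse = ", "),
         if (!is.null(weights$ratio)) paste0(" of ratio ", weights$ratio[1]))
  }
  -sum(weights$weight * log(transformed_p[weights$gene]))
}

#' Simulated null test of a weighted Fisher statistic
#'
#' Draws `n_sim` null statistics `X* = -sum_j w_ij ln(U_j)` with
#' `U_j ~ Uniform(0, 1)` i.i.d. (the rank transform makes the marginal null
#' exactly uniform) and estimates the upper-tail p-value with the add-one
#' estimator `(#(X* >= x_obs) + 1) / (n_sim + 1)`, which is always positive.
#'
#' @param weights Numeric vector of the ratio's gene weights.
#' @param x_obs Observed statistic.
#' @param n_sim Number of null draws (>= 100; the production default is
#'   100000).
#' @param seed Integer seed; identical inputs and seed give identical
#'   estimates.
#' @return A list with `x_obs`, `p` (in `[1/(n_sim+1), 1]`), `n_sim`,
#'   `seed`.
#' @export
simulate_null_and_test <- function(weights, x_obs, n_sim = 100000, seed = 1) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  k <- length(weights)
  x_null <- with_seed(seed, {
    u <- matrix(stats::runif(k * n_sim), nrow = k)
    as.numeric(crossprod(weights, -log(u)))
  })
  p <- (sum(x_null >= x_obs) + 1) / (n_sim + 1)
  list(x_obs = x_obs, p = p, n_sim = n_sim, seed = seed)
}

#' Reporter-ratio analysis of a gene statistics table
#'
#' End-to-end driver of the reporter statistic: maps genes to ratios on the
#' model, computes the three-step weights, rank-transforms the gene p-values
#' (over all genes in the supplied table), evaluates the weighted Fisher
#' statistic per ratio, and tests each against its own simulated null.
#'
#' @param model A `metabolic_model`.
#' @param gene_stats Data.frame with columns `gene` and `p` (plus anything
#'   else, carried along).
#' @param n_sim Null draws per ratio (default 100000).
#' @param seed Integer seed; each ratio uses an independent derived stream.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A data.frame: `ratio`, `met_a`, `met_b`, `n_genes`, `x`, `p_hat`,
#'   `significant`.
#' @export
reporter_analysis <- function(model, gene_stats, n_sim = 100000, seed = 1,
                              alpha = 0.05) {
  ratios <- build_ratio_gene_map(model)
  if (!nrow(ratios)) {
    return(data.frame(ratio = character(), met_a = character(),
                      met_b = character(), n_genes = integer(), x = numeric(),
                      p_hat = numeric(), significant = logical()))
  }
  wtab <- compute_weights(ratios)
  known <- setdiff(unique(wtab$gene), gene_stats$gene)
  if (length(known)) {
    stop("gene(s) in model without statistics: ", paste(known, collapse = ", "))
  }
  transformed <- stats::setNames(rank_inverse_uniform(gene_stats$p), gene_stats$gene)
  res <- lapply(seq_len(nrow(ratios)), function(i) {
    w <- wtab[wtab$ratio == ratios$ratio[i], , drop = FALSE]
    x <- weighted_fisher(w, transformed)
    nt <- simulate_null_and_test(w$weight, x, n_sim = n_sim,
                                 seed = substream_seed(seed, ratios$ratio[i]))
    data.frame(ratio = ratios$ratio[i], met_a = ratios$met_a[i],
               met_b = ratios$met_b[i], n_genes = ratios$n_genes[i],
               x = x, p_hat = nt$p, significant = nt$p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Reporter-selected metabolites
#'
#' The union of both member metabolites of every ratio with estimated
#' `p < alpha`; these are added to the path analysis as extra nodes.
#'
#' @param results Output of [reporter_analysis()].
#' @param alpha Significance level (default 0.05).
#' @return Character vector of metabolite ids (possibly empty).
#' @export
select_reporter_metabolites <- function(results, alpha = 0.05) {
  sel <- results$p_hat < alpha
  sort(unique(c(results$met_a[sel], results$met_b[sel])))
}
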