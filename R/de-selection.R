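#' Select differentially expressed genes
#'
#' Union selection rule: a gene is selected when `FDR < fdr_cut` or
#' `|log2FC| > lfc_cut`. The union reading is the one under which the two
#' published sub-counts (FDR-significant genes plus fold-change-only genes)
#' add up to the combined total. Selected genes are partitioned by fold
#' change sign; selected genes with exactly zero fold change are reported
#' separately rather than forced into a side.
#'
#' @param genes Data.frame with columns `gene`, `log2fc`, `fdr` (a `p`
#'   column, if present, is ignored by the rule).
#' @param fdr_cut FDR threshold (default 0.05, strict `<`).
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.5,
#'   strict `>`).
#' @return A list with character vectors `up`, `down` and `zero`.
#' @export
select_de_genes <- function(genes, fdr_cut = 0.05, lfc_cut = 0.5) {
  need <- c("gene", "log2fc", "fdr")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  selected <- genes$fdr < fdr_cut | abs(genes$log2fc) > lfc_cut
  list(up = genes$gene[selected & genes$log2fc > 0],
       down = genes$gene[selected & genes$log2fc < 0],
       zero = genes$gene[selected & genes$log2fc == 0])
}

#' Tabular I/O for the pipeline's standard formats
#'
#' Metabolite tables are TSV with a one-line header, first column `sample`,
#' second column `group`, then one numeric column per metabolite; gene
#' tables are TSV with columns `gene`, `p`, `log2fc`, `fdr`. Numbers are
#' serialized in full double precision.
#'
#' @param path File path.
#' @return A data.frame (readers); the path, invisibly (writers).
#' @export
read_metabolite_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(tab)[1:2])) {
    stop("metabolite table must start with 'sample' and 'group' columns")
  }
  m <- metabolite_matrix(tab)
  if (any(m < 0)) stop("negative concentrations in ", path)
  tab
}

#' @rdname read_metabolite_table
#' @param table A metabolite table.
#' @export
write_metabolite_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_metabolite_table
#' @export
read_gene_stats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "p", "log2fc", "fdr"), names(tab))
  if (length(miss)) stop("gene table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(tab$p < 0 | tab$p > 1)) stop("p-values outside [0, 1] in ", path)
  tab
}
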