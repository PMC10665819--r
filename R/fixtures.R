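#' Read a transcribed metabolite summary table
#'
#' Loads one of the shipped tissue-metabolite summary fixtures: per
#' metabolite the group means and SDs (ug/mg dry insoluble pellet) and the
#' printed significance mark counts of the underlying Mann-Whitney tests
#' (`stars_*` columns: 1/2/3 for p < 0.05/0.01/0.001 versus wildtype;
#' `hashes_treated_vs_disease` likewise versus the untreated disease group).
#' These are transcriptions of published summary statistics — the per-animal
#' values behind them are not public, so the marks are data, not something
#' the package recomputes.
#'
#' @param path Path to a summary TSV; see
#'   `system.file("extdata", package = "metabonet")` for the shipped tables.
#' @return A data.frame, one row per metabolite.
#' @export
read_metabolite_summary <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "wildtype_mean", "wildtype_sd", "disease_mean",
            "disease_sd", "treated_mean", "treated_sd",
            "stars_disease_vs_wildtype", "stars_treated_vs_wildtype",
            "hashes_treated_vs_disease")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("summary table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$metabolite)) stop("duplicated metabolite rows")
  tab
}

#' Count significance marks in a summary table
#'
#' @param summary A table from [read_metabolite_summary()].
#' @param comparison One of `"disease_vs_wildtype"`,
#'   `"treated_vs_wildtype"`, `"treated_vs_disease"`.
#' @return The number of metabolites carrying at least one mark for the
#'   comparison.
#' @export
count_significant_marks <- function(summary,
                                    comparison = c("disease_vs_wildtype",
                                                   "treated_vs_wildtype",
                                                   "treated_vs_disease")) {
  comparison <- match.arg(comparison)
  col <- switch(comparison,
                disease_vs_wildtype = "stars_disease_vs_wildtype",
                treated_vs_wildtype = "stars_treated_vs_wildtype",
                treated_vs_disease = "hashes_treated_vs_disease")
  sum(summary[[col]] > 0)
}
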