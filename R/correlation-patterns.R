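#' Per-group Pearson correlation matrices
#'
#' For every experimental group, Pearson r over all metabolite pairs with
#' two-sided p-values from the t distribution on `n - 2` degrees of freedom.
#' Constant metabolites within a group yield `NA` correlations (reported,
#' not dropped). The per-group matrices are the raw material for the
#' dual-significance pair filters.
#'
#' @param table A metabolite table; every group must have >= 4 samples.
#' @return An object of class `correlation_set`: a named list per group with
#'   elements `r`, `p` (symmetric matrices) and `n`.
#' @export
groupwise_pearson <- function(table) {
  m <- metabolite_matrix(table)
  groups <- unique(table$group)
  out <- lapply(groups, function(g) {
    sub <- m[table$group == g, , drop = FALSE]
    n <- nrow(sub)
    if (n < 4L) stop("group '", g, "' has fewer than 4 samples")
    r <- suppressWarnings(stats::cor(sub))  # NA for constant columns
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    diag(p) <- NA_real_
    list(r = r, p = p, n = n)
  })
  names(out) <- groups
  structure(out, class = "correlation_set")
}

#' Metabolite pairs significantly correlated in both groups of a comparison
#'
#' Implements the kept-correlation rule: only pairs whose correlation is
#' statistically significant (strict `p < alpha`) in *each* of the two groups
#' of the comparison are retained.
#'
#' @param mats A `correlation_set`.
#' @param comparison Character vector of two group names.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame with one row per unordered pair: `met_a`, `met_b`,
#'   `r_<group>` and `p_<group>` for both groups.
#' @export
shared_significant_pairs <- function(mats, comparison, alpha = 0.05) {
  stopifnot(length(comparison) == 2L)
  if (!all(comparison %in% names(mats))) {
    stop("comparison groups not in correlation set: ",
         paste(setdiff(comparison, names(mats)), collapse = ", "))
  }
  g1 <- mats[[comparison[1]]]; g2 <- mats[[comparison[2]]]
  mets <- colnames(g1$r)
  idx <- which(upper.tri(g1$r), arr.ind = TRUE)
  keep <- !is.na(g1$p[idx]) & !is.na(g2$p[idx]) &
    g1$p[idx] < alpha & g2$p[idx] < alpha
  idx <- idx[keep, , drop = FALSE]
  out <- data.frame(met_a = mets[idx[, 1]], met_b = mets[idx[, 2]],
                    stringsAsFactors = FALSE)
  out[[paste0("r_", comparison[1])]] <- g1$r[idx]
  out[[paste0("p_", comparison[1])]] <- g1$p[idx]
  out[[paste0("r_", comparison[2])]] <- g2$r[idx]
  out[[paste0("p_", comparison[2])]] <- g2$p[idx]
  out
}

#' Sign-concordance matrix of a comparison
#'
#' Over the dual-significant pairs only: `+1` when the correlation has the
#' same sign in both groups (both metabolites change in the same direction),
#' `-1` when the signs are opposite; every other cell is `NA`. The +/-1
#' values are categorical markers, not effect sizes.
#'
#' @inheritParams shared_significant_pairs
#' @return A symmetric numeric matrix with entries in `{+1, -1, NA}`.
#' @export
concordance_matrix <- function(mats, comparison, alpha = 0.05) {
  pairs <- shared_significant_pairs(mats, comparison, alpha)
  mets <- colnames(mats[[comparison[1]]]$r)
  out <- matrix(NA_real_, length(mets), length(mets),
                dimnames = list(mets, mets))
  if (nrow(pairs)) {
    s1 <- sign(pairs[[paste0("r_", comparison[1])]])
    s2 <- sign(pairs[[paste0("r_", comparison[2])]])
    val <- ifelse(s1 == s2, 1, -1)
    for (i in seq_len(nrow(pairs))) {
      out[pairs$met_a[i], pairs$met_b[i]] <- val[i]
      out[pairs$met_b[i], pairs$met_a[i]] <- val[i]
    }
  }
  out
}

#' Pairs with a treatment-specific correlation reversal
#'
#' Finds metabolite pairs whose correlation is significant in both the
#' disease and the treated group but with opposite signs, and which are
#' absent from the wildtype-disease concordance matrix (i.e. fail dual
#' significance there). The absence clause marks the reversal as
#' treatment-specific rather than disease-related.
#'
#' @param mats A `correlation_set` containing groups `wildtype`, `disease`
#'   and `disease_treated`.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame of pattern pairs with per-group r and p and
#'   `class = "opposite_under_treatment"`.
#' @export
find_opposite_treatment_pairs <- function(mats, alpha = 0.05) {
  groups <- c("wildtype", "disease", "disease_treated")
  if (!all(groups %in% names(mats))) {
    stop("correlation set must contain groups: ", paste(groups, collapse = ", "))
  }
  dt <- shared_significant_pairs(mats, c("disease", "disease_treated"), alpha)
  wd <- shared_significant_pairs(mats, c("wildtype", "disease"), alpha)
  opposite <- sign(dt$r_disease) != sign(dt$r_disease_treated)
  in_wd <- pair_key(dt$met_a, dt$met_b) %in% pair_key(wd$met_a, wd$met_b)
  out <- dt[opposite & !in_wd, , drop = FALSE]
  out <- annotate_group(out, mats, "wildtype")
  if (nrow(out)) out$class <- "opposite_under_treatment"
  rownames(out) <- NULL
  out
}

#' Pairs corrected toward the wildtype correlation by treatment
#'
#' Finds metabolite pairs with opposite-signed, dual-significant correlations
#' between wildtype and disease whose treated-group correlation is
#' dual-significant (with disease) and matches the wildtype sign — the
#' treatment restores the wildtype co-regulation pattern.
#'
#' @inheritParams find_opposite_treatment_pairs
#' @return A data.frame of pattern pairs with per-group r and p and
#'   `class = "corrected_toward_wildtype"`.
#' @export
find_corrected_pairs <- function(mats, alpha = 0.05) {
  groups <- c("wildtype", "disease", "disease_treated")
  if (!all(groups %in% names(mats))) {
    stop("correlation set must contain groups: ", paste(groups, collapse = ", "))
  }
  wd <- shared_significant_pairs(mats, c("wildtype", "disease"), alpha)
  dt <- shared_significant_pairs(mats, c("disease", "disease_treated"), alpha)
  opposite_wd <- sign(wd$r_wildtype) != sign(wd$r_disease)
  key_wd <- pair_key(wd$met_a, wd$met_b)
  key_dt <- pair_key(dt$met_a, dt$met_b)
  idx_dt <- match(key_wd, key_dt)
  corrected <- !is.na(idx_dt) &
    sign(dt$r_disease_treated[idx_dt]) == sign(wd$r_wildtype)
  out <- wd[opposite_wd & corrected, , drop = FALSE]
  sel <- idx_dt[opposite_wd & corrected]
  out$r_disease_treated <- dt$r_disease_treated[sel]
  out$p_disease_treated <- dt$p_disease_treated[sel]
  if (nrow(out)) out$class <- "corrected_toward_wildtype"
  rownames(out) <- NULL
  out
}

# Attach the r/p values of one extra group to a pair table.
annotate_group <- function(pairs, mats, group) {
  g <- mats[[group]]
  r <- numeric(nrow(pairs)); p <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r[i] <- g$r[pairs$met_a[i], pairs$met_b[i]]
    p[i] <- g$p[pairs$met_a[i], pairs$met_b[i]]
  }
  pairs[[paste0("r_", group)]] <- r
  pairs[[paste0("p_", group)]] <- p
  pairs
}
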