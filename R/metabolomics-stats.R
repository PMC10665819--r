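#' Convert a quantified concentration to tissue units
#'
#' NMR quantification reports mmol/L in the reconstitution buffer; tissue
#' concentrations are expressed per mg of dry insoluble pellet:
#' `c [mmol/L] x volume [mL] = nmol-scale amount in umol`, times the molar
#' mass in g/mol gives ug, divided by the pellet mass in mg.
#'
#' @param c_mmol_per_l Concentration in mmol/L (non-negative).
#' @param volume_ml Reconstitution volume in mL.
#' @param mw_g_per_mol Molecular weight in g/mol.
#' @param pellet_mg Dry insoluble pellet mass in mg (strictly positive).
#' @return Concentration in ug per mg pellet. Vectorized with recycling.
#' @examples
#' convert_concentration(1, 0.28, 100, 14)  # 2 ug/mg
#' @export
convert_concentration <- function(c_mmol_per_l, volume_ml, mw_g_per_mol, pellet_mg) {
  if (any(c_mmol_per_l < 0) || any(volume_ml < 0) || any(mw_g_per_mol < 0)) {
    stop("concentration, volume and molecular weight must be non-negative")
  }
  if (any(pellet_mg <= 0)) stop("pellet mass must be strictly positive")
  c_mmol_per_l * volume_ml * mw_g_per_mol / pellet_mg
}

# Pull the numeric concentration matrix out of a metabolite table
# (data.frame: sample, group, one column per metabolite).
metabolite_matrix <- function(table) {
  stopifnot(is.data.frame(table), all(c("sample", "group") %in% names(table)))
  m <- as.matrix(table[, setdiff(names(table), c("sample", "group")), drop = FALSE])
  rownames(m) <- table$sample
  storage.mode(m) <- "double"
  m
}

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution in the two-stage form the method was
#' introduced with: every sample is first scaled to unit total signal
#' (integral normalization), a reference profile is taken as the
#' element-wise median of the scaled samples (all samples by default, a
#' single group via `reference = "group:<name>"`), and each scaled sample is
#' then divided by the median of its per-metabolite quotients against that
#' reference. Because the pre-scaling makes the input to the quotient step
#' independent of any per-sample factor, the result is exactly invariant
#' under positive per-sample scaling of the input — `pqn(D %*% X)` equals
#' `pqn(X)` for any positive diagonal `D` — and exactly idempotent. The
#' output is on the dilution-adjusted share-of-total-signal scale (samples
#' proportional to their input profiles), which is the scale all downstream
#' between-group statistics use.
#'
#' @param table A metabolite table (data.frame with `sample`, `group`, then
#'   one numeric column per metabolite).
#' @param reference Reference policy: `"all-samples"` (default) or
#'   `"group:<name>"`.
#' @return The normalized table, same shape as the input.
#' @export
pqn_normalize <- function(table, reference = "all-samples") {
  m <- metabolite_matrix(table)
  if (nrow(m) < 2L) stop("PQN needs at least two samples")
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop("sample '", table$sample[which(totals <= 0)[1]],
         "' has no usable quotients (all-zero?)")
  }
  m <- m / totals
  ref_rows <- if (identical(reference, "all-samples")) {
    seq_len(nrow(m))
  } else if (startsWith(reference, "group:")) {
    grp <- sub("^group:", "", reference)
    rows <- which(table$group == grp)
    if (!length(rows)) stop("reference group not present: ", grp)
    rows
  } else {
    stop("unknown PQN reference policy: ", reference)
  }
  ref <- apply(m[ref_rows, , drop = FALSE], 2, stats::median)
  usable <- ref > 0
  factors <- vapply(seq_len(nrow(m)), function(i) {
    q <- m[i, usable] / ref[usable]
    q <- q[is.finite(q) & q > 0]
    if (!length(q)) {
      stop("sample '", table$sample[i], "' has no usable quotients (all-zero?)")
    }
    stats::median(q)
  }, numeric(1))
  m <- m / factors
  out <- table
  out[, colnames(m)] <- m
  out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test without any multiplicity adjustment. With
#' `length(a) + length(b) <= 12` and no ties the p-value comes from the exact
#' permutation distribution of U (doubled one-tailed tail probability, capped
#' at 1); otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @return A list with `U` (the smaller of the two U statistics), `p`
#'   (two-sided, uncorrected) and `exact` (logical, which branch was used).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) stop("each group needs at least 3 values")
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  u_b <- m * n - u_a
  u_min <- min(u_a, u_b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (m + n <= 12L && !ties) {
    # exact tail of the null permutation distribution of U
    p <- min(1, 2 * stats::pwilcox(u_min, m, n))
    list(U = u_min, p = p, exact = TRUE)
  } else {
    tie_tab <- table(r)
    correction <- sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1))
    sigma <- sqrt(m * n / 12 * (m + n + 1 - correction))
    mu <- m * n / 2
    z <- (abs(u_a - mu) - 0.5) / sigma  # continuity-corrected
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    list(U = u_min, p = p, exact = FALSE)
  }
}

#' Univariate metabolite screening between two groups
#'
#' Applies [mann_whitney()] per metabolite for one ordered group comparison
#' and reports the log2 fold change of arithmetic group means. P-values are
#' deliberately not corrected for multiple testing: the screen is exploratory
#' and a missed true effect is considered worse than a false positive.
#'
#' @param table A metabolite table.
#' @param comparison Character vector `c(numerator, denominator)` of group
#'   labels; the fold change is `log2(mean(numerator) / mean(denominator))`.
#' @param alpha Significance level for the flag (default 0.05, strict `<`).
#' @return A data.frame with columns `metabolite`, `comparison`, `U`, `p`,
#'   `log2fc`, `significant`. A zero mean in the denominator group yields
#'   `NA` fold change with a warning; the p-value is still computed.
#' @export
univariate_screen <- function(table, comparison, alpha = 0.05) {
  stopifnot(length(comparison) == 2L)
  if (!all(comparison %in% table$group)) {
    stop("comparison groups not all present: ", paste(comparison, collapse = ", "))
  }
  m <- metabolite_matrix(table)
  num <- m[table$group == comparison[1], , drop = FALSE]
  den <- m[table$group == comparison[2], , drop = FALSE]
  rows <- lapply(colnames(m), function(met) {
    mw <- mann_whitney(num[, met], den[, met])
    mean_den <- mean(den[, met])
    lfc <- if (mean_den == 0) {
      warning("metabolite '", met, "' has zero mean in denominator group; log2FC undefined")
      NA_real_
    } else {
      log2(mean(num[, met]) / mean_den)
    }
    data.frame(metabolite = met,
               comparison = paste(comparison, collapse = "_vs_"),
               U = mw$U, p = mw$p, log2fc = lfc,
               significant = mw$p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Principal component scores of a metabolite table
#'
#' Columns are centered and autoscaled to unit variance before singular value
#' decomposition; autoscaling matters because tissue metabolite
#' concentrations span several decades and raw-scale components would be
#' dominated by the most abundant species. Constant metabolite columns are
#' dropped with a warning before scaling.
#'
#' @param table A metabolite table.
#' @param k Number of components to return scores for.
#' @return A list with `scores` (samples x k), `explained` (variance
#'   fractions, all components, non-increasing), and `cumulative2` (percent
#'   variance of the first two components).
#' @export
pca_scores <- function(table, k = 2) {
  m <- metabolite_matrix(table)
  if (nrow(m) < 3L || ncol(m) < 2L) stop("PCA needs >= 3 samples and >= 2 metabolites")
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("dropping constant metabolite column(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(k, ncol(fit$x))
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       explained = explained,
       cumulative2 = 100 * sum(explained[seq_len(min(2, length(explained)))]))
}
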