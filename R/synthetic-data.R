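#' Configuration for the synthetic data generator
#'
#' Bundles and validates the knobs of the three-group generator. Defaults
#' emulate the design of a typical rodent tissue-metabolomics study:
#' around ten animals per group, log-normal measurement noise with a 20%
#' coefficient of variation, baseline concentrations spread over two decades,
#' and strongly left-skewed (`Beta(a, 1)`, `a < 1`) p-values for planted
#' signal genes.
#'
#' @param seed Integer seed; model topology, concentrations and gene
#'   p-values each use an independent sub-stream derived from it.
#' @param n_per_group Samples per group (>= 3; default 10).
#' @param metabolites Character vector of metabolite names for the
#'   concentration table.
#' @param metabolite_effects Named list: metabolite -> `list(group, shift)`,
#'   a multiplicative mean shift implanted in one group.
#' @param latent_factors List of factors driving correlation structure; each
#'   is `list(metabolites = c(m1, m2), loadings = list(wildtype = c(l1, l2),
#'   disease = ..., disease_treated = ...))`. Loadings are expressed in units
#'   of the log-noise standard deviation: a pair with loadings `(+2, +2)` in
#'   a group has within-group correlation `4 / 5 = 0.8` there; a zero loading
#'   removes the factor from that group.
#' @param signal_ratios Character vector of ratio ids (see
#'   [build_ratio_gene_map()]) whose genes receive transcriptomic signal.
#' @param signal_beta_a Shape of the `Beta(a, 1)` law for signal-gene
#'   p-values; must lie in `(0, 1]` (1 = no signal).
#' @param noise_cv Coefficient of variation of the log-normal noise (> 0).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_per_group = 10,
                             metabolites = sprintf("met%02d", 1:20),
                             metabolite_effects = list(),
                             latent_factors = list(),
                             signal_ratios = character(),
                             signal_beta_a = 0.1, noise_cv = 0.2) {
  if (n_per_group < 3) stop("n_per_group must be at least 3")
  if (noise_cv <= 0) stop("noise_cv must be positive")
  if (signal_beta_a <= 0 || signal_beta_a > 1) stop("signal_beta_a must lie in (0, 1]")
  unknown <- setdiff(names(metabolite_effects), metabolites)
  if (length(unknown)) {
    stop("metabolite effect(s) reference unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  }
  for (f in latent_factors) {
    if (!all(f$metabolites %in% metabolites)) {
      stop("latent factor references unknown metabolite(s): ",
           paste(setdiff(f$metabolites, metabolites), collapse = ", "))
    }
    if (!all(c("wildtype", "disease", "disease_treated") %in% names(f$loadings))) {
      stop("latent factor loadings must cover all three groups")
    }
  }
  structure(list(seed = seed, n_per_group = n_per_group,
                 metabolites = metabolites,
                 metabolite_effects = metabolite_effects,
                 latent_factors = latent_factors,
                 signal_ratios = signal_ratios,
                 signal_beta_a = signal_beta_a, noise_cv = noise_cv),
            class = "synthetic_config")
}

# Expected within-group correlation sign of a 2-metabolite factor.
factor_signs <- function(f) {
  vapply(c("wildtype", "disease", "disease_treated"), function(g) {
    l <- f$loadings[[g]]
    sign(l[1] * l[2])
  }, numeric(1))
}

classify_factor_pattern <- function(f) {
  s <- factor_signs(f)
  if (s[["wildtype"]] == 0 && s[["disease"]] != 0 &&
      s[["disease_treated"]] == -s[["disease"]]) {
    "opposite_under_treatment"
  } else if (s[["wildtype"]] != 0 && s[["disease"]] == -s[["wildtype"]] &&
             s[["disease_treated"]] == s[["wildtype"]]) {
    "corrected_toward_wildtype"
  } else {
    "other"
  }
}

#' Simulate a three-group metabolite concentration table
#'
#' Concentrations are log-normal around a log-uniform baseline (two decades),
#' with per-group multiplicative mean shifts from `metabolite_effects` and
#' correlation structure implanted through shared latent factors with
#' group-specific loading signs. The factor construction guarantees a
#' positive-definite covariance in every group and exact control of the
#' implanted correlation sign per group.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `table` (data.frame: `sample`, `group`, metabolite
#'   columns) and `truth` (list with `shifted_metabolites`, `pattern_pairs`).
#' @export
simulate_metabolite_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  groups <- c("wildtype", "disease", "disease_treated")
  n <- cfg$n_per_group
  mets <- cfg$metabolites
  sigma <- sqrt(log(1 + cfg$noise_cv^2))

  with_seed(substream_seed(cfg$seed, "table"), {
    baseline <- 10^stats::runif(length(mets), -1.5, 0.5)
    names(baseline) <- mets

    shift <- matrix(1, nrow = 3, ncol = length(mets),
                    dimnames = list(groups, mets))
    for (met in names(cfg$metabolite_effects)) {
      eff <- cfg$metabolite_effects[[met]]
      shift[eff$group, met] <- eff$shift
    }

    rows <- list()
    for (g in groups) {
      logc <- matrix(stats::rnorm(n * length(mets), 0, sigma), nrow = n)
      logc <- sweep(logc, 2, log(baseline * shift[g, ]), `+`)
      colnames(logc) <- mets
      for (f in cfg$latent_factors) {
        l <- f$loadings[[g]]
        if (all(l == 0)) next
        scores <- stats::rnorm(n)
        for (j in seq_along(f$metabolites)) {
          logc[, f$metabolites[j]] <-
            logc[, f$metabolites[j]] + l[j] * sigma * scores
        }
      }
      rows[[g]] <- data.frame(sample = sprintf("%s_%02d", g, seq_len(n)),
                              group = g, exp(logc),
                              stringsAsFactors = FALSE, check.names = FALSE)
    }
    table <- do.call(rbind, rows)
    rownames(table) <- NULL

    pattern_pairs <- lapply(cfg$latent_factors, function(f) {
      list(pair = pair_key(f$metabolites[1], f$metabolites[2]),
           metabolites = f$metabolites,
           class = classify_factor_pattern(f),
           signs = factor_signs(f))
    })
    shifted <- names(cfg$metabolite_effects)[
      vapply(cfg$metabolite_effects, function(e) e$shift != 1, logical(1))]
    list(table = table,
         truth = list(shifted_metabolites = shifted,
                      pattern_pairs = pattern_pairs))
  })
}

#' Simulate a gene-level statistics table for a model
#'
#' Emulates the output table of an upstream differential-expression run over
#' the genes of `model`. Genes attached to the configured signal ratios draw
#' p-values from `Beta(a, 1)` (left-skewed, `a < 1`); all other genes draw
#' from `Uniform(0, 1)`. Fold-change magnitudes decrease monotonically with
#' the p-value, with random sign; FDR is Benjamini-Hochberg.
#'
#' @param model A `metabolic_model`.
#' @param cfg A [synthetic_config()]; `cfg$signal_ratios` must be ratio ids
#'   derivable from the model.
#' @return A list with `gene_stats` (data.frame: `gene`, `p`, `log2fc`,
#'   `fdr`) and `truth` (list with `signal_ratios`, `signal_genes`).
#' @export
simulate_gene_stats <- function(model, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ratios <- suppressMessages(build_ratio_gene_map(model))
  bad <- setdiff(cfg$signal_ratios, ratios$ratio)
  if (length(bad)) {
    stop("signal ratio(s) not derivable from the model: ",
         paste(bad, collapse = ", "))
  }
  genes <- sort(unique(unlist(lapply(model$reactions, `[[`, "genes"))))
  signal_genes <- sort(unique(unlist(
    ratios$genes[ratios$ratio %in% cfg$signal_ratios])))

  with_seed(substream_seed(cfg$seed, "genes"), {
    p <- stats::runif(length(genes))
    is_signal <- genes %in% signal_genes
    # Beta(a, 1) via inverse CDF: U^(1/a)
    p[is_signal] <- stats::runif(sum(is_signal))^(1 / cfg$signal_beta_a)
    lfc <- sample(c(-1, 1), length(genes), replace = TRUE) *
      abs(stats::qnorm(pmax(p, 1e-300) / 2)) / 3
    gene_stats <- data.frame(gene = genes, p = p, log2fc = lfc,
                             fdr = stats::p.adjust(p, "BH"),
                             stringsAsFactors = FALSE)
    list(gene_stats = gene_stats,
         truth = list(signal_ratios = cfg$signal_ratios,
                      signal_genes = signal_genes))
  })
}

#' Synthetic differential-expression benchmark table
#'
#' A fully synthetic gene table constructed to match the published marginal
#' counts of the treated-vs-disease comparison it emulates: 81 genes with
#' FDR < 0.05 (35 with positive and 46 with negative fold change, 58 of
#' which also flagged in the disease-vs-wildtype comparison), 103 additional
#' genes with |log2FC| > 0.5 but FDR >= 0.05 (20 positive, 83 negative), and
#' a uniform null background. No per-gene value is real; only the marginal
#' counts are meaningful. Used to exercise the selection rule
#' ([select_de_genes()]) and the overlap arithmetic at the published sizes.
#'
#' @param seed Integer seed for the (irrelevant) within-stratum values.
#' @param n_background Number of null background genes (default 800).
#' @return A data.frame with columns `gene`, `p`, `log2fc`, `fdr`,
#'   `sig_disease_vs_wildtype`.
#' @export
make_de_benchmark <- function(seed = 1, n_background = 800) {
  with_seed(substream_seed(seed, "de-benchmark"), {
    strata <- list(
      # FDR-significant, positive fold change (any magnitude)
      list(n = 35, fdr = function(n) stats::runif(n, 1e-6, 0.049),
           lfc = function(n) stats::runif(n, 0.05, 2)),
      # FDR-significant, negative fold change
      list(n = 46, fdr = function(n) stats::runif(n, 1e-6, 0.049),
           lfc = function(n) -stats::runif(n, 0.05, 2)),
      # fold-change-only, up
      list(n = 20, fdr = function(n) stats::runif(n, 0.051, 1),
           lfc = function(n) stats::runif(n, 0.51, 2)),
      # fold-change-only, down
      list(n = 83, fdr = function(n) stats::runif(n, 0.051, 1),
           lfc = function(n) -stats::runif(n, 0.51, 2)),
      # null background
      list(n = n_background, fdr = function(n) stats::runif(n, 0.051, 1),
           lfc = function(n) stats::runif(n, -0.49, 0.49)))
    tab <- do.call(rbind, lapply(seq_along(strata), function(i) {
      s <- strata[[i]]
      data.frame(stratum = i, fdr = s$fdr(s$n), log2fc = s$lfc(s$n),
                 stringsAsFactors = FALSE)
    }))
    tab$gene <- sprintf("gene%04d", seq_len(nrow(tab)))
    tab$p <- tab$fdr * stats::runif(nrow(tab), 0.2, 1)
    # 58 of the 81 FDR-significant genes overlap the wildtype comparison
    sig_idx <- which(tab$stratum %in% 1:2)
    wt_sig <- rep(FALSE, nrow(tab))
    wt_sig[sample(sig_idx, 58)] <- TRUE
    other <- setdiff(seq_len(nrow(tab)), sig_idx)
    wt_sig[sample(other, min(200, length(other)))] <- TRUE
    tab$sig_disease_vs_wildtype <- wt_sig
    tab[, c("gene", "p", "log2fc", "fdr", "sig_disease_vs_wildtype")]
  })
}
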