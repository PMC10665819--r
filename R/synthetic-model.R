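#' Generate a toy stoichiometric model
#'
#' Builds a small but structurally complete metabolic model for testing:
#' carbon-bearing core metabolites in equal-carbon partner pairs (so every
#' conversion is carbon-balanced by construction), a NAD-like redox couple
#' registered as a cofactor pair, a gene-less membrane transporter, at least
#' one irreversible reaction, a carbon-free water-like species, a SAM-like
#' hub entry, and gene associations on every enzymatic reaction. Output is
#' deterministic for a fixed seed; topology, concentrations and gene
#' p-values elsewhere in the generator use independent derived streams.
#'
#' @param seed Integer seed.
#' @param n_core_metabolites Number of core carbon metabolites (>= 4).
#' @param n_reactions Number of reactions (>= 3; the first three are the
#'   fixed transporter, irreversible and redox reactions).
#' @return A `metabolic_model`.
#' @export
make_toy_model <- function(seed, n_core_metabolites = 8, n_reactions = 6) {
  if (n_core_metabolites < 4) stop("need at least 4 core metabolites")
  if (n_reactions < 3) stop("need at least 3 reactions")
  with_seed(substream_seed(seed, "model"), {
    n_pairs <- floor(n_core_metabolites / 2)
    pair_carbons <- sample(3:6, n_pairs, replace = TRUE)
    carbons <- rep(pair_carbons, each = 2)[seq_len(2 * n_pairs)]
    if (n_core_metabolites %% 2 == 1L) carbons <- c(carbons, sample(3:6, 1))

    core_ids <- sprintf("met%02d_c", seq_len(n_core_metabolites))
    core <- data.frame(
      id = core_ids,
      name = sprintf("metabolite %02d", seq_len(n_core_metabolites)),
      species = sprintf("met%02d", seq_len(n_core_metabolites)),
      compartment = "c",
      formula = sprintf("C%dH%dO%d", carbons, 2 * carbons, pmax(1, carbons - 1)),
      stringsAsFactors = FALSE)
    core$synonyms <- I(lapply(core$species, function(s) paste0(s, "-syn")))

    extra <- data.frame(
      id = c("met01_e", "nad_c", "nadh_c", "h2o_c", "sam_c"),
      name = c("metabolite 01", "NAD+", "NADH", "water", "S-adenosylmethionine"),
      species = c("met01", "nad", "nadh", "h2o", "sam"),
      compartment = c("e", "c", "c", "c", "c"),
      formula = c(core$formula[1], "C21H27N7O14P2", "C21H28N7O14P2",
                  "H2O", "C15H22N6O5S"),
      stringsAsFactors = FALSE)
    extra$synonyms <- I(list(character(), "NAD", "NADH2", "HOH", "SAM"))
    mets <- rbind(core, extra)

    gene_pool <- sprintf("g%02d", seq_len(max(4, n_reactions)))
    pick_genes <- function() sort(sample(gene_pool, sample(1:2, 1)))
    # partner of metabolite i within its equal-carbon pair
    partner_pairs <- lapply(seq_len(n_pairs), function(k) core_ids[c(2 * k - 1, 2 * k)])

    reactions <- list(
      list(id = "r01_transport",
           stoichiometry = c(met01_e = -1, met01_c = 1),
           reversible = TRUE, transporter = TRUE, genes = character(),
           half_reactions = list(list(substrates = "met01_e", products = "met01_c"))),
      list(id = "r02_irreversible",
           stoichiometry = stats::setNames(c(-1, 1, 1),
                                           c(partner_pairs[[2]][1], partner_pairs[[2]][2], "h2o_c")),
           reversible = FALSE, transporter = FALSE, genes = pick_genes(),
           half_reactions = list(list(substrates = partner_pairs[[2]][1],
                                      products = c(partner_pairs[[2]][2], "h2o_c")))),
      list(id = "r03_redox",
           stoichiometry = stats::setNames(c(-1, -1, 1, 1),
                                           c(partner_pairs[[1]][1], "nad_c", partner_pairs[[1]][2], "nadh_c")),
           reversible = TRUE, transporter = FALSE, genes = pick_genes(),
           half_reactions = list(
             list(substrates = partner_pairs[[1]][1], products = partner_pairs[[1]][2]),
             list(substrates = "nad_c", products = "nadh_c"))))

    for (i in seq_len(n_reactions - 3L)) {
      template <- sample(c("conversion", "transaminase"), 1,
                         prob = c(0.6, 0.4))
      if (template == "conversion" || n_pairs < 2L) {
        pp <- sample(partner_pairs, 1)[[1]]
        if (stats::runif(1) < 0.5) pp <- rev(pp)
        rxn <- list(
          id = sprintf("r%02d_conv", i + 3L),
          stoichiometry = stats::setNames(c(-1, 1), pp),
          reversible = stats::runif(1) < 0.6, transporter = FALSE,
          genes = pick_genes(),
          half_reactions = list(list(substrates = pp[1], products = pp[2])))
      } else {
        two <- sample(partner_pairs, 2)
        a <- two[[1]]; x <- two[[2]]
        rxn <- list(
          id = sprintf("r%02d_trans", i + 3L),
          stoichiometry = stats::setNames(c(-1, -1, 1, 1),
                                          c(a[1], x[1], a[2], x[2])),
          reversible = stats::runif(1) < 0.6, transporter = FALSE,
          genes = pick_genes(),
          half_reactions = list(
            list(substrates = a[1], products = a[2]),
            list(substrates = x[1], products = x[2])))
      }
      reactions[[length(reactions) + 1L]] <- rxn
    }

    metabolic_model(mets, reactions,
                    cofactor_pairs = list(c("nadh_c", "nad_c")),
                    hubs = "sam_c")
  })
}
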