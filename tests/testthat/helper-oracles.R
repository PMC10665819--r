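# Hand-built models and independent oracles used across the suite.

# Textbook two-half-reaction model: a lactate dehydrogenase reaction
# (redox couple decoupled from the carbon skeleton), a transaminase,
# a methyltransferase touching the SAM hub, and a hydratase using water.
ldh_model <- function() {
  mets <- data.frame(
    id = c("nadh_c", "nad_c", "pyr_c", "lac_c", "glu_c", "akg_c", "ala_c",
           "sam_c", "sah_c", "fum_c", "mal_c", "h2o_c"),
    name = c("NADH", "NAD+", "pyruvate", "lactate", "glutamate",
             "2-oxoglutarate", "alanine", "S-adenosylmethionine",
             "S-adenosylhomocysteine", "fumarate", "malate", "water"),
    species = c("nadh", "nad", "pyr", "lac", "glu", "akg", "ala",
                "sam", "sah", "fum", "mal", "h2o"),
    compartment = "c",
    formula = c("C21H28N7O14P2", "C21H27N7O14P2", "C3H4O3", "C3H6O3",
                "C5H9NO4", "C5H6O5", "C3H7NO2", "C15H22N6O5S",
                "C14H20N6O5S", "C4H4O4", "C4H6O5", "H2O"),
    stringsAsFactors = FALSE)
  mets$synonyms <- I(list("NADH2", c("NAD", "DPN"), "pyruvic acid",
                          "lactic acid", "glutamic acid", "AKG",
                          "L-alanine", "SAM", "SAH", "fumaric acid",
                          c("malic acid", "L-malate"), character()))
  rxns <- list(
    list(id = "r_ldh",
         stoichiometry = c(nadh_c = -1, pyr_c = -1, nad_c = 1, lac_c = 1),
         reversible = TRUE, transporter = FALSE, genes = "Ldha",
         half_reactions = list(
           list(substrates = "nadh_c", products = "nad_c"),
           list(substrates = "pyr_c", products = "lac_c"))),
    list(id = "r_alt",
         stoichiometry = c(glu_c = -1, pyr_c = -1, akg_c = 1, ala_c = 1),
         reversible = TRUE, transporter = FALSE, genes = c("Gpt", "Gpt2"),
         half_reactions = list(
           list(substrates = "glu_c", products = "akg_c"),
           list(substrates = "pyr_c", products = "ala_c"))),
    list(id = "r_mt",
         stoichiometry = c(sam_c = -1, pyr_c = -1, sah_c = 1, lac_c = 1),
         reversible = FALSE, transporter = FALSE, genes = "Mtx",
         half_reactions = list(
           list(substrates = "sam_c", products = "sah_c"),
           list(substrates = "pyr_c", products = "lac_c"))),
    list(id = "r_fh",
         stoichiometry = c(fum_c = -1, h2o_c = -1, mal_c = 1),
         reversible = TRUE, transporter = FALSE, genes = "Fh1",
         half_reactions = list(
           list(substrates = c("fum_c", "h2o_c"), products = "mal_c"))))
  metabolic_model(mets, rxns,
                  cofactor_pairs = list(c("nadh_c", "nad_c")),
                  hubs = "sam_c")
}

# Minimal three-group metabolite table built directly from matrices.
group_table <- function(wildtype, disease, treated) {
  stack <- function(m, g) {
    data.frame(sample = sprintf("%s_%02d", g, seq_len(nrow(m))), group = g, m,
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- rbind(stack(wildtype, "wildtype"), stack(disease, "disease"),
               stack(treated, "disease_treated"))
  rownames(out) <- NULL
  out
}

# Exact Mann-Whitney p by full enumeration of all group labelings:
# two-sided p = 2 * P(U <= observed min-U) over all C(m+n, m) labelings.
mw_enumeration_p <- function(a, b) {
  vals <- c(a, b)
  m <- length(a)
  n <- length(b)
  r <- rank(vals)
  u1_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  obs <- min(u1_of(seq_len(m)), m * n - u1_of(seq_len(m)))
  tail1 <- mean(apply(utils::combn(m + n, m), 2, function(idx) u1_of(idx) <= obs))
  list(U = obs, p = min(1, 2 * tail1))
}

# Independent path enumerator: igraph vertex paths expanded over parallel
# edges, then filtered by the weight, zero-run and cost rules.
oracle_paths <- function(a, b, model, max_cost = 2, max_zero_run = 2,
                         cutoff = 8) {
  edges <- pair_edges(model)
  if (!nrow(edges)) return(character())
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = model$metabolites$id))
  vpaths <- suppressWarnings(
    igraph::all_simple_paths(g, from = a, to = b, mode = "out", cutoff = cutoff))
  sigs <- character()
  for (vp in vpaths) {
    verts <- names(vp)
    slots <- lapply(seq_len(length(verts) - 1L), function(i) {
      which(edges$from == verts[i] & edges$to == verts[i + 1L])
    })
    if (any(lengths(slots) == 0L)) next
    combos <- expand.grid(slots, KEEP.OUT.ATTRS = FALSE)
    for (ci in seq_len(nrow(combos))) {
      eidx <- as.integer(combos[ci, ])
      w <- edges$weight[eidx]
      if (sum(w) > max_cost || sum(w) < 1) next
      zero_runs <- rle(w == 0)
      if (any(zero_runs$values & zero_runs$lengths > max_zero_run)) next
      sigs <- c(sigs, paste(
        paste(verts, collapse = "|"),
        paste(edges$reaction[eidx], collapse = "|"), sum(w), sep = "::"))
    }
  }
  sort(unique(sigs))
}

# The same signature for find_paths output, for set comparison.
path_sigs <- function(paths) {
  sort(unique(vapply(paths, function(p) {
    paste(paste(p$metabolites, collapse = "|"),
          paste(p$reactions, collapse = "|"), p$cost, sep = "::")
  }, "")))
}

extdata <- function(name) {
  system.file("extdata", name, package = "metabonet", mustWork = TRUE)
}
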