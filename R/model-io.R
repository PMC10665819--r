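#' Construct a stoichiometric metabolic model
#'
#' The model is the substrate for substrate-product pair extraction and path
#' finding. Metabolite ids are compartment-qualified (e.g. `"pyr_c"`); the
#' `species` field carries the compartment-free identity so that transporter
#' reactions (the only cross-compartment edges) can be validated. Hub
#' metabolites (ubiquitous currency species such as H+, H2O, ATP and SAM) are
#' never linkable, which prevents the network collapsing into a single
#' ball around them.
#'
#' @param metabolites A data.frame with columns `id`, `name`, `species`,
#'   `compartment`, `formula`, and optionally `synonyms` (list column),
#'   `chebi`, `hub` (logical).
#' @param reactions A list of reactions; each a list with `id`,
#'   `stoichiometry` (named numeric, negative = substrate), `reversible`,
#'   `transporter`, `genes` (character), and optionally `half_reactions`
#'   (list of `list(substrates =, products =)` id sets). A reaction without a
#'   declared half-reaction partition is treated as a single whole-reaction
#'   couple when pairs are extracted.
#' @param cofactor_pairs List of length-2 character vectors of metabolite ids;
#'   couples (e.g. a NAD-like redox couple) that are always linkable within
#'   their own half-reaction even when the carbon rule alone would not apply.
#' @param hubs Character vector of hub metabolite ids.
#' @return An object of class `metabolic_model`. The set of uniquely produced
#'   metabolites (appearing as a product of exactly one reaction, model-wide)
#'   is computed on construction and stored in `$uniquely_produced`.
#' @seealso [load_model()], [extract_pairs()], [find_paths()]
#' @export
metabolic_model <- function(metabolites, reactions, cofactor_pairs = list(),
                            hubs = character()) {
  stopifnot(is.data.frame(metabolites), is.list(reactions))
  need <- c("id", "name", "species", "compartment", "formula")
  miss <- setdiff(need, names(metabolites))
  if (length(miss)) stop("metabolites table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metabolites$id)) stop("duplicated metabolite ids")
  if (is.null(metabolites$synonyms)) metabolites$synonyms <- I(rep(list(character()), nrow(metabolites)))
  if (is.null(metabolites$chebi)) metabolites$chebi <- NA_character_
  metabolites$carbon <- carbon_count(metabolites$formula)
  metabolites$hub <- metabolites$id %in% hubs

  ids <- metabolites$id
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids)) stop("duplicated reaction ids")
  for (r in reactions) {
    s <- r$stoichiometry
    bad <- setdiff(names(s), ids)
    if (length(bad)) {
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    }
    if (!any(s < 0) || !any(s > 0)) {
      stop("reaction '", r$id, "' must have at least one substrate and one product")
    }
    if (isTRUE(r$transporter)) {
      sp <- metabolites$species[match(names(s), ids)]
      cmp <- metabolites$compartment[match(names(s), ids)]
      if (length(unique(sp)) != 1L || length(unique(cmp)) < 2L) {
        stop("transporter '", r$id,
             "' must move one species between distinct compartments")
      }
    }
    if (!is.null(r$half_reactions)) {
      for (h in r$half_reactions) {
        hs <- c(h$substrates, h$products)
        if (!all(hs %in% names(s))) {
          stop("half-reaction of '", r$id, "' references metabolites outside its stoichiometry")
        }
      }
    }
  }
  for (cp in cofactor_pairs) {
    if (length(cp) != 2L || !all(cp %in% ids)) stop("invalid cofactor pair")
  }
  linkable <- unlist(cofactor_pairs)
  if (length(intersect(hubs, linkable))) {
    stop("hub metabolites cannot appear in the cofactor-pair registry")
  }

  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         cofactor_pairs = cofactor_pairs, hubs = hubs,
         uniquely_produced = character()),
    class = "metabolic_model")
  model$uniquely_produced <- uniquely_produced(model)
  model
}

#' Uniquely produced metabolites of a model
#'
#' A metabolite is uniquely produced when it appears on the product side of
#' exactly one reaction, counted over the whole model with reactions in their
#' written (forward) direction. Producing half-reactions of such metabolites
#' get weight zero in path finding, on the rationale that a metabolite with a
#' single biosynthetic source is informationally tied to its product.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of metabolite ids.
#' @export
uniquely_produced <- function(model) {
  prod_counts <- table(unlist(lapply(model$reactions, function(r) {
    names(r$stoichiometry)[r$stoichiometry > 0]
  })))
  names(prod_counts)[prod_counts == 1L]
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions,",
      length(x$cofactor_pairs), "cofactor pairs,",
      length(x$hubs), "hubs\n")
  invisible(x)
}

#' Read / write a metabolic model in the package's JSON dialect
#'
#' The dialect has four top-level keys: `metabolites` (objects with `id`,
#' `name`, `species`, `compartment`, `formula`, `synonyms`, `chebi`),
#' `reactions` (objects with `id`, `stoichiometry`, `reversible`,
#' `transporter`, `genes`, `half_reactions`), `cofactor_pairs`, and `hubs`.
#' Writing canonicalizes the file (entries sorted by id, fixed key order), so
#' `write_model(load_model(f))` is byte-stable.
#'
#' @param path File path.
#' @return `load_model` returns a `metabolic_model`; `write_model` returns
#'   `path` invisibly.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = m$name, species = m$species,
               compartment = m$compartment, formula = m$formula,
               chebi = if (length(m$chebi)) m$chebi else NA_character_,
               stringsAsFactors = FALSE)
  }))
  mets$synonyms <- I(lapply(doc$metabolites, function(m) {
    as.character(unlist(m$synonyms))
  }))
  rxns <- lapply(doc$reactions, function(r) {
    list(id = r$id,
         stoichiometry = unlist(r$stoichiometry),
         reversible = isTRUE(r$reversible),
         transporter = isTRUE(r$transporter),
         genes = as.character(unlist(r$genes)),
         half_reactions = if (length(r$half_reactions)) {
           lapply(r$half_reactions, function(h) {
             list(substrates = as.character(unlist(h$substrates)),
                  products = as.character(unlist(h$products)))
           })
         })
  })
  metabolic_model(
    metabolites = mets, reactions = rxns,
    cofactor_pairs = lapply(doc$cofactor_pairs, function(p) as.character(unlist(p))),
    hubs = as.character(unlist(doc$hubs)))
}

#' @rdname load_model
#' @param model A `metabolic_model`.
#' @export
write_model <- function(model, path) {
  mets <- model$metabolites[order(model$metabolites$id), , drop = FALSE]
  met_list <- lapply(seq_len(nrow(mets)), function(i) {
    ml <- list(id = mets$id[i], name = mets$name[i], species = mets$species[i],
               compartment = mets$compartment[i], formula = mets$formula[i],
               synonyms = as.list(mets$synonyms[[i]]), chebi = mets$chebi[i])
    if (is.na(ml$chebi)) ml$chebi <- NULL
    ml
  })
  rxns <- model$reactions[order(vapply(model$reactions, `[[`, "", "id"))]
  rxn_list <- lapply(rxns, function(r) {
    st <- r$stoichiometry[order(names(r$stoichiometry))]
    list(id = r$id, stoichiometry = as.list(st),
         reversible = r$reversible, transporter = r$transporter,
         genes = as.list(sort(r$genes)),
         half_reactions = lapply(r$half_reactions %||% list(), function(h) {
           list(substrates = as.list(sort(h$substrates)),
                products = as.list(sort(h$products)))
         }))
  })
  doc <- list(metabolites = met_list, reactions = rxn_list,
              cofactor_pairs = lapply(model$cofactor_pairs, function(p) as.list(sort(p))),
              hubs = as.list(sort(model$hubs)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Map measured metabolite names onto model metabolites
#'
#' Measured names (as reported by the quantification platform) rarely match
#' model ids directly; matching is done on a normalized form — lower case,
#' punctuation, whitespace and charge symbols stripped — against primary
#' names and all synonyms. Ambiguous names (normalizing to more than one
#' metabolite species) are reported, never silently resolved.
#'
#' @param names Character vector of measured metabolite names.
#' @param model A `metabolic_model`.
#' @return A list with `mapping` (data.frame `name`, `metabolite_id`),
#'   `unmatched` (character) and `ambiguous` (data.frame `name`, `candidates`).
#' @export
map_measured_metabolites <- function(names, model) {
  norm <- function(x) gsub("[^a-z0-9]", "", gsub("[+-]+$", "", tolower(trimws(x))))
  mets <- model$metabolites
  lut <- do.call(rbind, lapply(seq_len(nrow(mets)), function(i) {
    keys <- unique(norm(c(mets$name[i], mets$synonyms[[i]])))
    data.frame(key = keys, id = mets$id[i], species = mets$species[i],
               stringsAsFactors = FALSE)
  }))
  mapping <- data.frame(name = character(), metabolite_id = character(),
                        stringsAsFactors = FALSE)
  unmatched <- character()
  ambiguous <- data.frame(name = character(), candidates = character(),
                          stringsAsFactors = FALSE)
  for (nm in names) {
    hits <- lut[lut$key == norm(nm), , drop = FALSE]
    n_species <- length(unique(hits$species))
    if (nrow(hits) == 0L) {
      unmatched <- c(unmatched, nm)
    } else if (n_species > 1L) {
      ambiguous <- rbind(ambiguous, data.frame(
        name = nm, candidates = paste(unique(hits$id), collapse = ";"),
        stringsAsFactors = FALSE))
    } else {
      mapping <- rbind(mapping, data.frame(
        name = nm, metabolite_id = hits$id[1], stringsAsFactors = FALSE))
    }
  }
  list(mapping = mapping, unmatched = unmatched, ambiguous = ambiguous)
}
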