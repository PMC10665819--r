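#' Extract linkable substrate-product pairs from a reaction
#'
#' Metabolites are linked only within a half-reaction of the reaction's
#' declared partition, which decouples electron, amino and phosphate transfer
#' couples from the main carbon skeleton: in
#' `NADH + pyruvate <=> NAD+ + lactate` with partition
#' `{NADH -> NAD+}, {pyruvate -> lactate}`, NADH links to NAD+ and pyruvate
#' to lactate, but pyruvate never links to NAD+. Within a half-reaction a
#' substrate links a product iff both carry carbon and neither is a hub, or
#' the two are a registered cofactor couple. Transporter reactions and
#' producing half-reactions of uniquely produced metabolites yield
#' weight-zero pairs (they are free moves in path finding); all other pairs
#' have weight one. Irreversible reactions give forward-only pairs.
#'
#' @param reaction A reaction entry of `model$reactions` (or its id).
#' @param model A `metabolic_model`.
#' @return A data.frame with columns `reaction`, `substrate`, `product`,
#'   `weight` (0 or 1) and `direction` (`"forward"` or `"either"`);
#'   zero rows when nothing is linkable.
#' @export
extract_pairs <- function(reaction, model) {
  if (is.character(reaction)) {
    idx <- match(reaction, vapply(model$reactions, `[[`, "", "id"))
    if (is.na(idx)) stop("unknown reaction: ", reaction)
    reaction <- model$reactions[[idx]]
  }
  st <- reaction$stoichiometry
  halves <- reaction$half_reactions
  if (is.null(halves) || !length(halves)) {
    warning("reaction '", reaction$id,
            "' has no half-reaction partition; treating it as one couple")
    halves <- list(list(substrates = names(st)[st < 0],
                        products = names(st)[st > 0]))
  }
  mets <- model$metabolites
  carbon <- stats::setNames(mets$carbon, mets$id)
  is_hub <- stats::setNames(mets$hub, mets$id)
  cof_keys <- vapply(model$cofactor_pairs, function(p) pair_key(p[1], p[2]), "")
  dir <- if (reaction$reversible) "either" else "forward"

  out <- list()
  for (h in halves) {
    produces_unique <- any(h$products %in% model$uniquely_produced)
    w <- if (isTRUE(reaction$transporter) || produces_unique) 0 else 1
    for (s in h$substrates) {
      for (p in h$products) {
        cof <- pair_key(s, p) %in% cof_keys
        carbon_ok <- carbon[s] > 0 && carbon[p] > 0 && !is_hub[s] && !is_hub[p]
        if (cof || carbon_ok) {
          out[[length(out) + 1L]] <- data.frame(
            reaction = reaction$id, substrate = s, product = p,
            weight = w, direction = dir, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(reaction = character(), substrate = character(),
                      product = character(), weight = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' All linkable pairs of a model
#'
#' Convenience wrapper applying [extract_pairs()] to every reaction.
#'
#' @inheritParams extract_pairs
#' @param warn Pass `FALSE` to silence the missing-partition warning.
#' @return Row-bound pair table (see [extract_pairs()]).
#' @export
model_pairs <- function(model, warn = TRUE) {
  f <- if (warn) identity else suppressWarnings
  do.call(rbind, lapply(model$reactions, function(r) f(extract_pairs(r, model))))
}

#' Map genes onto the metabolite ratios they can affect
#'
#' Each distinct unordered substrate-product pair (a "metabolite ratio")
#' collects the union of the gene associations of every reaction that yields
#' it. Ratios whose contributing reactions carry no genes (e.g. spontaneous
#' or transporter pairs) cannot receive transcriptomic evidence and are
#' excluded with a message.
#'
#' @param model A `metabolic_model`.
#' @return A data.frame with columns `ratio` (canonical `"a~b"` key), `met_a`,
#'   `met_b`, `genes` (list column) and `n_genes`.
#' @export
build_ratio_gene_map <- function(model) {
  pairs <- model_pairs(model, warn = FALSE)
  if (!nrow(pairs)) {
    return(data.frame(ratio = character(), met_a = character(),
                      met_b = character(), n_genes = integer()))
  }
  pairs$ratio <- pair_key(pairs$substrate, pairs$product)
  gene_lut <- lapply(model$reactions, `[[`, "genes")
  names(gene_lut) <- vapply(model$reactions, `[[`, "", "id")

  keys <- unique(pairs$ratio)
  rows <- lapply(keys, function(k) {
    sub <- pairs[pairs$ratio == k, , drop = FALSE]
    genes <- sort(unique(unlist(gene_lut[unique(sub$reaction)])))
    ab <- strsplit(k, "~", fixed = TRUE)[[1]]
    list(ratio = k, met_a = ab[1], met_b = ab[2], genes = genes)
  })
  n_genes <- vapply(rows, function(r) length(r$genes), integer(1))
  if (any(n_genes == 0L)) {
    message("excluding ", sum(n_genes == 0L),
            " ratio(s) without gene associations: ",
            paste(keys[n_genes == 0L], collapse = ", "))
  }
  rows <- rows[n_genes > 0L]
  out <- data.frame(
    ratio = vapply(rows, `[[`, "", "ratio"),
    met_a = vapply(rows, `[[`, "", "met_a"),
    met_b = vapply(rows, `[[`, "", "met_b"),
    stringsAsFactors = FALSE)
  out$genes <- I(lapply(rows, `[[`, "genes"))
  out$n_genes <- vapply(out$genes, length, integer(1))
  out
}
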