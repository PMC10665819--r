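#' Directed pair-graph edge list of a model
#'
#' Expands the linkable substrate-product pairs into directed edges:
#' every pair gives a forward edge, and reversible reactions also give the
#' reverse edge. This is the graph on which [find_paths()] searches.
#'
#' @param model A `metabolic_model`.
#' @param pairs Optionally a precomputed [model_pairs()] table.
#' @return A data.frame with columns `from`, `to`, `reaction`, `weight`.
#' @export
pair_edges <- function(model, pairs = NULL) {
  if (is.null(pairs)) pairs <- model_pairs(model, warn = FALSE)
  fwd <- data.frame(from = pairs$substrate, to = pairs$product,
                    reaction = pairs$reaction, weight = pairs$weight,
                    stringsAsFactors = FALSE)
  rev <- pairs[pairs$direction == "either", , drop = FALSE]
  if (nrow(rev)) {
    fwd <- rbind(fwd, data.frame(from = rev$product, to = rev$substrate,
                                 reaction = rev$reaction, weight = rev$weight,
                                 stringsAsFactors = FALSE))
  }
  unique(fwd)
}

#' Find constrained biochemical paths between two metabolites
#'
#' Enumerates all simple paths (no metabolite revisited) from `a` to `b` over
#' the directed pair graph whose total weight is between 1 and `max_cost`.
#' Weight-one steps are ordinary biochemical conversions; weight-zero steps
#' (transporters, producing half-reactions of uniquely produced metabolites)
#' are free but at most `max_zero_run` may occur consecutively, which keeps
#' the search finite and mirrors the fact that transporters chain at most
#' cytosol-organelle-extracellular in practice. Irreversible reactions are
#' traversed forward only.
#'
#' @param a,b Metabolite ids (endpoints), `a != b`.
#' @param model A `metabolic_model`.
#' @param max_cost Maximum total path weight (default 2: "one or two
#'   reaction steps").
#' @param edges Optionally a precomputed [pair_edges()] table.
#' @param max_zero_run Maximum run of consecutive zero-weight steps.
#' @return A list of paths; each path is a list with `metabolites` (the node
#'   sequence, starting at `a` and ending at `b`), `reactions`, `weights` and
#'   `cost`. Empty list when `b` is unreachable.
#' @export
find_paths <- function(a, b, model, max_cost = 2, edges = NULL,
                       max_zero_run = 2) {
  if (identical(a, b)) stop("endpoints must differ")
  ids <- model$metabolites$id
  if (!a %in% ids || !b %in% ids) stop("both endpoints must be in the model")
  if (is.null(edges)) edges <- pair_edges(model)
  if (!nrow(edges)) return(list())
  adj <- split(seq_len(nrow(edges)), edges$from)

  results <- list()
  recurse <- function(node, visited, rxns, wts, cost, zero_run) {
    out_edges <- adj[[node]]
    for (i in out_edges) {
      nxt <- edges$to[i]
      if (nxt %in% visited) next
      w <- edges$weight[i]
      new_cost <- cost + w
      if (new_cost > max_cost) next
      new_zero <- if (w == 0) zero_run + 1L else 0L
      if (new_zero > max_zero_run) next
      path_rxns <- c(rxns, edges$reaction[i])
      path_wts <- c(wts, w)
      if (nxt == b) {
        if (new_cost >= 1) {
          results[[length(results) + 1L]] <<- list(
            metabolites = c(visited, nxt), reactions = path_rxns,
            weights = path_wts, cost = new_cost)
        }
        next  # a simple path cannot leave b and end at b again
      }
      recurse(nxt, c(visited, nxt), path_rxns, path_wts, new_cost, new_zero)
    }
  }
  recurse(a, a, character(), numeric(), 0, 0L)
  results
}

# Canonical string form of a path, identical for a path and its reversal,
# used to deduplicate edges found from both endpoints of a reversible route.
path_signature <- function(path) {
  fwd <- paste(c(rbind(path$metabolites[-length(path$metabolites)], path$reactions),
                 path$metabolites[length(path$metabolites)]), collapse = "|")
  rev_m <- rev(path$metabolites)
  rev_r <- rev(path$reactions)
  bwd <- paste(c(rbind(rev_m[-length(rev_m)], rev_r), rev_m[length(rev_m)]),
               collapse = "|")
  min(fwd, bwd)
}
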