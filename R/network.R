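#' Assemble the annotated metabolite network
#'
#' Builds the displayable network: nodes are the measured metabolites, the
#' declared bridge metabolites (unmeasured central-metabolism intermediates
#' added to prevent gaps in the classical pathways), any reporter-selected
#' metabolites, and the genes of every reaction appearing on a kept path.
#' Edges are all constrained paths ([find_paths()]) between metabolite node
#' pairs, deduplicated so a reversible route is stored once. Gene nodes are
#' attached to the endpoints of the edges whose reactions they catalyze, and
#' connected components are labeled over the whole graph.
#'
#' @param measured Character vector of measured metabolite ids (non-empty).
#' @param bridges Character vector of bridge metabolite ids.
#' @param model A `metabolic_model`.
#' @param reporter Character vector of reporter-selected metabolite ids
#'   (see [select_reporter_metabolites()]).
#' @param annotations Optional named list with elements `metabolites` and/or
#'   `genes`: data.frames keyed by `id` whose remaining columns (p-values,
#'   log2 fold changes, significance flags) are carried onto the nodes.
#' @param max_cost Maximum path weight (default 2).
#' @return An object of class `metabolite_network`: a list with `nodes`
#'   (id, type, role, component, annotation columns), `edges` (from, to,
#'   via, reactions, cost, component) and `gene_links` (gene, metabolite).
#' @export
build_network <- function(measured, bridges = character(), model,
                          reporter = character(), annotations = NULL,
                          max_cost = 2) {
  if (!length(measured)) stop("measured metabolite set is empty")
  met_nodes <- unique(c(measured, bridges, reporter))
  missing <- setdiff(met_nodes, model$metabolites$id)
  if (length(missing)) {
    stop("metabolites not in model: ", paste(missing, collapse = ", "))
  }
  edges_tab <- pair_edges(model)

  paths <- list()
  seen <- character()
  for (u in met_nodes) {
    for (v in setdiff(met_nodes, u)) {
      for (p in find_paths(u, v, model, max_cost = max_cost, edges = edges_tab)) {
        sig <- path_signature(p)
        if (!sig %in% seen) {
          seen <- c(seen, sig)
          paths[[length(paths) + 1L]] <- p
        }
      }
    }
  }

  edge_df <- if (length(paths)) {
    data.frame(
      from = vapply(paths, function(p) p$metabolites[1], ""),
      to = vapply(paths, function(p) p$metabolites[length(p$metabolites)], ""),
      via = vapply(paths, function(p)
        paste(p$metabolites[-c(1, length(p$metabolites))], collapse = ";"), ""),
      reactions = vapply(paths, function(p) paste(p$reactions, collapse = ";"), ""),
      cost = vapply(paths, function(p) p$cost, numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), via = character(),
               reactions = character(), cost = numeric(),
               stringsAsFactors = FALSE)
  }

  rxn_genes <- lapply(model$reactions, `[[`, "genes")
  names(rxn_genes) <- vapply(model$reactions, `[[`, "", "id")
  gene_links <- data.frame(gene = character(), metabolite = character(),
                           stringsAsFactors = FALSE)
  if (nrow(edge_df)) {
    for (i in seq_len(nrow(edge_df))) {
      genes <- unique(unlist(rxn_genes[strsplit(edge_df$reactions[i], ";")[[1]]]))
      for (g in genes) {
        gene_links <- rbind(gene_links, data.frame(
          gene = g, metabolite = c(edge_df$from[i], edge_df$to[i]),
          stringsAsFactors = FALSE))
      }
    }
    gene_links <- unique(gene_links)
  }

  nodes <- data.frame(
    id = c(met_nodes, unique(gene_links$gene)),
    type = c(rep("metabolite", length(met_nodes)),
             rep("gene", length(unique(gene_links$gene)))),
    stringsAsFactors = FALSE)
  nodes$role <- ifelse(nodes$type == "gene", "gene",
                ifelse(nodes$id %in% measured, "measured",
                ifelse(nodes$id %in% bridges, "bridge", "reporter")))

  # component labels over metabolite-metabolite edges plus gene attachments
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(nodes), name = nodes$id)
  ep <- rbind(as.matrix(edge_df[, c("from", "to")]),
              as.matrix(gene_links[, c("gene", "metabolite")]))
  if (nrow(ep)) g <- igraph::add_edges(g, t(ep))
  comp <- igraph::components(g)$membership
  nodes$component <- unname(comp[nodes$id])
  edge_df$component <- unname(comp[edge_df$from])

  if (!is.null(annotations)) {
    for (kind in c("metabolites", "genes")) {
      ann <- annotations[[kind]]
      if (is.null(ann)) next
      idx <- match(nodes$id, ann$id)
      for (col in setdiff(names(ann), "id")) {
        nodes[[col]] <- if (col %in% names(nodes)) {
          ifelse(is.na(idx), nodes[[col]], ann[[col]][idx])
        } else {
          ann[[col]][idx]
        }
      }
    }
  }

  structure(list(nodes = nodes, edges = edge_df, gene_links = gene_links),
            class = "metabolite_network")
}

#' @export
print.metabolite_network <- function(x, ...) {
  cat("metabolite_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$type == "metabolite"), "metabolites,",
      sum(x$nodes$type == "gene"), "genes ),",
      nrow(x$edges), "edges,",
      length(unique(x$nodes$component)), "components\n")
  invisible(x)
}

#' Drop under-supported subnetworks
#'
#' Removes every connected component containing at most `min_significant - 1`
#' significant nodes (genes and metabolites counted together). Components
#' meeting the threshold are retained whole, including their non-significant
#' members; the operation never splits a component and is idempotent.
#'
#' @param net A `metabolite_network`.
#' @param significant Character vector of significant node ids (subset of the
#'   network's nodes).
#' @param min_significant Minimum number of significant nodes a component
#'   needs to survive (default 3, i.e. components with only one or two
#'   significant members are dropped).
#' @return The filtered `metabolite_network`.
#' @export
filter_subnetworks <- function(net, significant, min_significant = 3) {
  bad <- setdiff(significant, net$nodes$id)
  if (length(bad)) stop("significant ids not in network: ", paste(bad, collapse = ", "))
  sig_per_comp <- tapply(net$nodes$id %in% significant, net$nodes$component, sum)
  keep <- as.numeric(names(sig_per_comp))[sig_per_comp >= min_significant]
  nodes <- net$nodes[net$nodes$component %in% keep, , drop = FALSE]
  edges <- net$edges[net$edges$component %in% keep, , drop = FALSE]
  gl <- net$gene_links[net$gene_links$gene %in% nodes$id &
                         net$gene_links$metabolite %in% nodes$id, , drop = FALSE]
  structure(list(nodes = nodes, edges = edges, gene_links = gl),
            class = "metabolite_network")
}

#' Export / import a metabolite network
#'
#' `export_graph` writes the network with all node and edge annotations as
#' node-link JSON (default) or GraphML; `import_graph` reads the JSON form
#' back. The JSON payload has `nodes` and `links` arrays in the style
#' consumed by common web graph viewers.
#'
#' @param net A `metabolite_network`.
#' @param path Output file path.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly; `import_graph` returns a `metabolite_network`.
#' @export
export_graph <- function(net, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      nodes = lapply(seq_len(nrow(net$nodes)), function(i) {
        row <- as.list(net$nodes[i, , drop = FALSE])
        lapply(row, function(v) if (is.na(v)) NULL else v)
      }),
      links = lapply(seq_len(nrow(net$edges)), function(i) {
        list(source = net$edges$from[i], target = net$edges$to[i],
             via = net$edges$via[i], reactions = net$edges$reactions[i],
             cost = net$edges$cost[i], component = net$edges$component[i])
      }),
      gene_links = lapply(seq_len(nrow(net$gene_links)), function(i) {
        list(gene = net$gene_links$gene[i],
             metabolite = net$gene_links$metabolite[i])
      }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::add_vertices(g, nrow(net$nodes), name = net$nodes$id,
                              type = net$nodes$type, role = net$nodes$role,
                              component = net$nodes$component)
    if (nrow(net$edges)) {
      g <- igraph::add_edges(g, t(as.matrix(net$edges[, c("from", "to")])),
                             reactions = net$edges$reactions,
                             cost = net$edges$cost)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path) {
  doc <- jsonlite::read_json(path)
  to_df <- function(items) {
    if (!length(items)) return(NULL)
    cols <- unique(unlist(lapply(items, names)))
    out <- lapply(cols, function(cn) {
      vals <- lapply(items, function(it) it[[cn]] %||% NA)
      unlist(vals)
    })
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  nodes <- to_df(doc$nodes)
  links <- to_df(doc$links)
  edges <- if (is.null(links)) {
    data.frame(from = character(), to = character(), via = character(),
               reactions = character(), cost = numeric(),
               component = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(from = links$source, to = links$target, via = links$via,
               reactions = links$reactions, cost = links$cost,
               component = links$component, stringsAsFactors = FALSE)
  }
  gl <- to_df(doc$gene_links)
  if (is.null(gl)) gl <- data.frame(gene = character(), metabolite = character(),
                                    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, gene_links = gl),
            class = "metabolite_network")
}
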