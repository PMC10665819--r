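test_that("model I/O round-trips and validates references", {
  model <- make_toy_model(1, 8, 6)
  f1 <- tempfile(fileext = ".json")
  write_model(model, f1)
  reloaded <- load_model(f1)
  f2 <- tempfile(fileext = ".json")
  write_model(reloaded, f2)
  expect_identical(readLines(f1), readLines(f2))

  # dangling metabolite reference is a schema error naming the reaction
  bad <- jsonlite::read_json(f1)
  bad$reactions[[2]]$stoichiometry$ghost_c <- -1
  fb <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, fb, auto_unbox = TRUE)
  expect_error(load_model(fb), "ghost_c")

  # empty reaction side rejected
  one_sided <- jsonlite::read_json(f1)
  st <- one_sided$reactions[[2]]$stoichiometry
  one_sided$reactions[[2]]$stoichiometry <- lapply(st, function(x) abs(x))
  fo <- tempfile(fileext = ".json")
  jsonlite::write_json(one_sided, fo, auto_unbox = TRUE)
  expect_error(load_model(fo), "substrate")
})

test_that("uniquely produced metabolites are those with exactly one producing reaction", {
  model <- ldh_model()
  # mal_c is produced only by r_fh; lac_c by r_ldh and r_mt (not unique)
  expect_true("mal_c" %in% model$uniquely_produced)
  expect_false("lac_c" %in% model$uniquely_produced)
})

test_that("measured-name mapping normalizes charge and punctuation", {
  model <- ldh_model()
  res <- map_measured_metabolites(
    c("NAD", "Pyruvic Acid", "sn-glycero-3-phosphocholine", "L-Malate"), model)
  expect_equal(res$mapping$metabolite_id[res$mapping$name == "NAD"], "nad_c")
  expect_equal(res$mapping$metabolite_id[res$mapping$name == "Pyruvic Acid"], "pyr_c")
  expect_equal(res$mapping$metabolite_id[res$mapping$name == "L-Malate"], "mal_c")
  expect_equal(res$unmatched, "sn-glycero-3-phosphocholine")
})

test_that("pair extraction respects half-reactions, carbon, hubs and cofactors", {
  model <- ldh_model()
  ldh <- extract_pairs("r_ldh", model)
  got <- pair_key(ldh$substrate, ldh$product)
  expect_setequal(got, c("nad_c~nadh_c", "lac_c~pyr_c"))
  expect_false("nad_c~pyr_c" %in% got)  # never across half-reactions

  alt <- extract_pairs("r_alt", model)
  expect_setequal(pair_key(alt$substrate, alt$product),
                  c("akg_c~glu_c", "ala_c~pyr_c"))

  # SAM is a hub: its half-reaction yields no SAM pair
  mt <- extract_pairs("r_mt", model)
  expect_false(any(mt$substrate == "sam_c" | mt$product == "sam_c"))
  expect_true(all(mt$direction[mt$reaction == "r_mt"] == "forward"))

  # water carries no carbon: no water pair; fum-mal remains
  fh <- extract_pairs("r_fh", model)
  expect_setequal(pair_key(fh$substrate, fh$product), "fum_c~mal_c")
  # mal_c is uniquely produced -> its producing half-reaction has weight 0
  expect_equal(fh$weight, 0)

  # reaction without partition: whole-reaction couple with a warning
  no_part <- model
  no_part$reactions[[1]]$half_reactions <- NULL
  expect_warning(whole <- extract_pairs(no_part$reactions[[1]], no_part),
                 "partition")
  expect_true("nad_c~pyr_c" %in% pair_key(whole$substrate, whole$product))
})

test_that("path finding matches the printed chain examples", {
  # chain A ->(r1) B ->(r2) C plus a zero-weight transporter in front;
  # d_c feeds B and C a second time so neither is uniquely produced and
  # the chain reactions keep weight 1
  mets <- data.frame(
    id = c("a_e", "a_c", "b_c", "c_c", "d_c"),
    name = c("A", "A", "B", "C", "D"), species = c("a", "a", "b", "c", "d"),
    compartment = c("e", "c", "c", "c", "c"),
    formula = "C3H6O3", stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "t1", stoichiometry = c(a_e = -1, a_c = 1), reversible = TRUE,
         transporter = TRUE, genes = character(),
         half_reactions = list(list(substrates = "a_e", products = "a_c"))),
    list(id = "r1", stoichiometry = c(a_c = -1, b_c = 1), reversible = FALSE,
         transporter = FALSE, genes = "g1",
         half_reactions = list(list(substrates = "a_c", products = "b_c"))),
    list(id = "r2", stoichiometry = c(b_c = -1, c_c = 1), reversible = TRUE,
         transporter = FALSE, genes = "g2",
         half_reactions = list(list(substrates = "b_c", products = "c_c"))),
    list(id = "r3", stoichiometry = c(d_c = -1, b_c = 1), reversible = FALSE,
         transporter = FALSE, genes = "g3",
         half_reactions = list(list(substrates = "d_c", products = "b_c"))),
    list(id = "r4", stoichiometry = c(d_c = -1, c_c = 1), reversible = FALSE,
         transporter = FALSE, genes = "g4",
         half_reactions = list(list(substrates = "d_c", products = "c_c"))))
  chain <- metabolic_model(mets, rxns)

  ac <- find_paths("a_c", "c_c", chain)
  expect_length(ac, 1L)
  expect_equal(ac[[1]]$reactions, c("r1", "r2"))
  expect_equal(ac[[1]]$cost, 2)

  ab <- find_paths("a_c", "b_c", chain)
  expect_length(ab, 1L)
  expect_equal(ab[[1]]$cost, 1)

  # zero-weight transporter step does not count toward the cost
  aeb <- find_paths("a_e", "b_c", chain)
  expect_length(aeb, 1L)
  expect_equal(aeb[[1]]$reactions, c("t1", "r1"))
  expect_equal(aeb[[1]]$cost, 1)

  # irreversible r1 cannot be traversed backwards
  expect_length(find_paths("b_c", "a_c", chain), 0L)
  expect_error(find_paths("a_c", "a_c", chain), "differ")
})

test_that("path finding equals exhaustive enumeration on random toy models", {
  set.seed(99)
  for (seed in 1:20) {
    model <- make_toy_model(seed, sample(6:12, 1), sample(5:15, 1))
    ids <- model$metabolites$id
    for (rep in 1:4) {
      ab <- sample(ids, 2)
      got <- path_sigs(find_paths(ab[1], ab[2], model))
      want <- oracle_paths(ab[1], ab[2], model)
      expect_identical(got, want)
    }
  }
})

test_that("reversible-only models give mirror-image path sets", {
  model <- ldh_model()
  model$reactions <- lapply(model$reactions, function(r) {
    r$reversible <- TRUE
    r
  })
  model <- metabolic_model(model$metabolites, model$reactions,
                           model$cofactor_pairs, model$hubs)
  fwd <- find_paths("pyr_c", "akg_c", model)
  bwd <- find_paths("akg_c", "pyr_c", model)
  rev_sig <- sort(vapply(bwd, function(p) {
    paste(paste(rev(p$metabolites), collapse = "|"),
          paste(rev(p$reactions), collapse = "|"), p$cost, sep = "::")
  }, ""))
  expect_identical(path_sigs(fwd), rev_sig)
})

test_that("paths never touch hub metabolites or cross half-reactions", {
  for (seed in 1:5) {
    model <- make_toy_model(seed, 8, 10)
    hubs <- model$hubs
    pairs <- model_pairs(model, warn = FALSE)
    expect_false(any(pairs$substrate %in% hubs | pairs$product %in% hubs))
    for (r in model$reactions) {
      rp <- pairs[pairs$reaction == r$id, , drop = FALSE]
      for (i in seq_len(nrow(rp))) {
        in_same_half <- any(vapply(r$half_reactions, function(h) {
          (rp$substrate[i] %in% h$substrates && rp$product[i] %in% h$products)
        }, logical(1)))
        expect_true(in_same_half)
      }
    }
  }
})

test_that("network assembly connects through declared bridges and labels components", {
  mets <- data.frame(
    id = c("a_c", "g6p_c", "b_c", "x_c", "y_c", "a2_c"),
    name = c("A", "glucose-6-phosphate", "B", "X", "Y", "A2"),
    species = c("a", "g6p", "b", "x", "y", "a2"), compartment = "c",
    formula = c("C6H12O6", "C6H13O9P", "C6H12O6", "C3H6O3", "C3H6O3", "C6H12O6"),
    stringsAsFactors = FALSE)
  # a2_c feeds g6p_c and b_c so neither is uniquely produced
  rxns <- list(
    list(id = "r1", stoichiometry = c(a_c = -1, g6p_c = 1), reversible = TRUE,
         transporter = FALSE, genes = "g1",
         half_reactions = list(list(substrates = "a_c", products = "g6p_c"))),
    list(id = "r2", stoichiometry = c(g6p_c = -1, b_c = 1), reversible = TRUE,
         transporter = FALSE, genes = "g2",
         half_reactions = list(list(substrates = "g6p_c", products = "b_c"))),
    list(id = "r3", stoichiometry = c(x_c = -1, y_c = 1), reversible = TRUE,
         transporter = FALSE, genes = "g3",
         half_reactions = list(list(substrates = "x_c", products = "y_c"))),
    list(id = "r4", stoichiometry = c(a2_c = -1, g6p_c = 1), reversible = FALSE,
         transporter = FALSE, genes = "g4",
         half_reactions = list(list(substrates = "a2_c", products = "g6p_c"))),
    list(id = "r5", stoichiometry = c(a2_c = -1, b_c = 1), reversible = FALSE,
         transporter = FALSE, genes = "g5",
         half_reactions = list(list(substrates = "a2_c", products = "b_c"))))
  model <- metabolic_model(mets, rxns)

  # with the glycolytic intermediate declared as bridge, A and B connect
  with_bridge <- build_network(c("a_c", "b_c"), bridges = "g6p_c", model = model)
  comp <- with_bridge$nodes$component
  names(comp) <- with_bridge$nodes$id
  expect_equal(comp[["a_c"]], comp[["b_c"]])

  # without the bridge they stay apart (two-step a->g6p->b still links them),
  # so check a model where the two-step route is too long instead
  no_bridge <- build_network(c("a_c", "x_c"), model = model)
  compn <- no_bridge$nodes$component
  names(compn) <- no_bridge$nodes$id
  expect_false(compn[["a_c"]] == compn[["x_c"]])

  # gene nodes ride along with their reactions
  expect_true(all(c("g1", "g2") %in% with_bridge$nodes$id))

  # component labels equal igraph's on the same edge set
  g <- igraph::graph_from_data_frame(
    rbind(with_bridge$edges[, c("from", "to")],
          stats::setNames(with_bridge$gene_links, c("from", "to"))),
    directed = FALSE,
    vertices = data.frame(name = with_bridge$nodes$id))
  ref <- igraph::components(g)$membership
  grp_pkg <- unname(lapply(split(with_bridge$nodes$id, with_bridge$nodes$component), sort))
  grp_ref <- unname(lapply(split(names(ref), ref), sort))
  expect_setequal(grp_pkg, grp_ref)

  expect_error(build_network(character(), model = model), "empty")
})

test_that("subnetwork filtering drops weakly supported components and is idempotent", {
  model <- make_toy_model(1, 8, 8)
  measured <- grep("^met0[1-8]_c$", model$metabolites$id, value = TRUE)
  net <- build_network(measured, model = model)
  comps <- split(net$nodes$id, net$nodes$component)
  # pick significance so one component passes (3 nodes) and others fail
  big <- comps[[which.max(lengths(comps))]]
  sig <- head(big, 3)
  kept <- filter_subnetworks(net, significant = sig)
  expect_true(all(big %in% kept$nodes$id))
  expect_false(any(setdiff(net$nodes$id, big) %in% kept$nodes$id))
  # boundary: exactly 2 significant nodes -> dropped
  kept2 <- filter_subnetworks(net, significant = head(big, 2))
  expect_false(any(big %in% kept2$nodes$id))
  # idempotence and no component splitting
  again <- filter_subnetworks(kept, significant = sig)
  expect_identical(again$nodes$id, kept$nodes$id)
  expect_identical(again$edges, kept$edges)
  # empty network in, empty network out
  empty <- filter_subnetworks(net, significant = character())
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(filter_subnetworks(empty, character())$nodes), 0L)
})

test_that("graph export round-trips nodes and edges", {
  model <- make_toy_model(2, 8, 8)
  measured <- grep("^met0[1-8]_c$", model$metabolites$id, value = TRUE)
  net <- build_network(measured, model = model)
  f <- tempfile(fileext = ".json")
  export_graph(net, f)
  back <- import_graph(f)
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(nrow(back$edges), nrow(net$edges))
  expect_setequal(paste(back$edges$from, back$edges$to, back$edges$reactions),
                  paste(net$edges$from, net$edges$to, net$edges$reactions))

  fg <- tempfile(fileext = ".graphml")
  export_graph(net, fg, format = "graphml")
  g <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
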