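# Helper: a ratio table in the shape of build_ratio_gene_map() output.
ratio_table <- function(spec) {
  out <- data.frame(ratio = names(spec), stringsAsFactors = FALSE)
  ab <- strsplit(names(spec), "~", fixed = TRUE)
  out$met_a <- vapply(ab, `[`, "", 1)
  out$met_b <- vapply(ab, `[`, "", 2)
  out$genes <- I(unname(spec))
  out$n_genes <- lengths(spec)
  out
}

test_that("ratio-gene map unions genes over contributing reactions", {
  model <- ldh_model()
  ratios <- suppressMessages(build_ratio_gene_map(model))
  # lac~pyr arises from r_ldh (Ldha) and r_mt (Mtx): union of both gene sets
  lp <- ratios[ratios$ratio == "lac_c~pyr_c", ]
  expect_setequal(lp$genes[[1]], c("Ldha", "Mtx"))
  # single-reaction pair keeps its own genes
  expect_setequal(ratios$genes[[which(ratios$ratio == "akg_c~glu_c")]],
                  c("Gpt", "Gpt2"))
  expect_equal(ratios$n_genes[ratios$ratio == "nad_c~nadh_c"], 1L)

  # a gene-less transporter pair is excluded with a log message
  tmod <- make_toy_model(1, 8, 6)
  expect_message(build_ratio_gene_map(tmod), "without gene associations")
})

test_that("three-step weight normalization matches the hand trace", {
  # R1{g1, g2}, R2{g1}: step 2 gives 0.5/0.5 and 1; step 3 rescales per gene
  ratios <- ratio_table(list("a~b" = c("g1", "g2"), "b~c" = "g1"))
  w <- compute_weights(ratios)
  get <- function(r, g) w$weight[w$ratio == r & w$gene == g]
  expect_equal(get("a~b", "g1"), 0.5)
  expect_equal(get("b~c", "g1"), 1)
  expect_equal(get("a~b", "g2"), 1)

  # invariants: weights in (0, 1], per-gene maximum exactly 1
  model <- make_toy_model(5, 10, 12)
  rr <- suppressMessages(build_ratio_gene_map(model))
  ww <- compute_weights(rr)
  expect_true(all(ww$weight > 0 & ww$weight <= 1))
  expect_true(all(abs(tapply(ww$weight, ww$gene, max) - 1) < 1e-12))

  # single ratio: all weights rescale to one regardless of gene count
  single <- ratio_table(list("a~b" = c("g1", "g2", "g3")))
  expect_equal(compute_weights(single)$weight, c(1, 1, 1))

  # a gene in k equal-size ratios keeps weight 1 in all of them
  sym <- ratio_table(list("a~b" = c("g1", "g2"), "c~d" = c("g1", "g3")))
  ws <- compute_weights(sym)
  expect_equal(ws$weight[ws$gene == "g1"], c(1, 1))
})

test_that("rank-inverse-uniform transform matches worked examples and is rank-invariant", {
  expect_equal(rank_inverse_uniform(c(0.01, 0.5, 0.9)), c(0.25, 0.5, 0.75))
  expect_equal(rank_inverse_uniform(c(0.02, 0.8, 0.4, 0.4)),
               c(0.2, 0.8, 0.5, 0.5))
  p <- runif(50)
  expect_equal(rank_inverse_uniform(p), rank_inverse_uniform(p^3))
  out <- rank_inverse_uniform(p)
  expect_true(all(out > 0 & out < 1))
  expect_error(rank_inverse_uniform(numeric()), "empty")
  expect_error(rank_inverse_uniform(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("weighted Fisher statistic matches hand arithmetic", {
  w1 <- data.frame(ratio = "a~b", gene = "g1", weight = 1)
  expect_equal(weighted_fisher(w1, c(g1 = exp(-1))), 1)

  w2 <- data.frame(ratio = "a~b", gene = c("g1", "g2"), weight = c(0.5, 1))
  expect_equal(weighted_fisher(w2, c(g1 = 0.25, g2 = 0.5)),
               -0.5 * log(0.25) - log(0.5))

  # near-one p-values drive the statistic to zero
  expect_lt(weighted_fisher(w2, c(g1 = 1 - 1e-12, g2 = 1 - 1e-12)), 1e-10)

  expect_error(weighted_fisher(w2, c(g1 = 0.5)), "g2")
})

test_that("statistic is monotone: improving a gene's rank never lowers X", {
  w <- data.frame(ratio = "a~b", gene = c("g1", "g2", "g3"),
                  weight = c(0.3, 0.6, 1))
  p <- c(g1 = 0.4, g2 = 0.2, g3 = 0.7)
  base <- weighted_fisher(w, p)
  for (g in names(p)) {
    better <- p
    better[g] <- better[g] / 2
    expect_gte(weighted_fisher(w, better), base)
  }
})

test_that("simulated null test is calibrated, deterministic and bounded", {
  # single gene, weight 1: P(X* >= -ln 0.05) = 0.05 exactly
  res <- simulate_null_and_test(1, -log(0.05), n_sim = 20000, seed = 10)
  se <- sqrt(0.05 * 0.95 / 20000)
  expect_lt(abs(res$p - 0.05), 3 * se)

  # x_obs = 0 is below every draw -> p = 1
  expect_equal(simulate_null_and_test(c(0.5, 1), 0, n_sim = 500, seed = 1)$p, 1)

  # determinism and the add-one lower bound
  a <- simulate_null_and_test(c(0.5, 1), 5, n_sim = 1000, seed = 7)
  b <- simulate_null_and_test(c(0.5, 1), 5, n_sim = 1000, seed = 7)
  expect_identical(a, b)
  huge <- simulate_null_and_test(1, 1e6, n_sim = 500, seed = 2)
  expect_equal(huge$p, 1 / 501)

  expect_error(simulate_null_and_test(1, 1, n_sim = 50), "at least 100")
})

test_that("equal-weight nulls follow the scaled chi-square law", {
  for (k in c(2L, 5L)) {
    null_draws <- local({
      set.seed(123 + k)
      u <- matrix(runif(k * 20000), nrow = k)
      colSums(-log(u))
    })
    for (q in c(0.5, 0.9, 0.95, 0.99)) {
      closed <- stats::qchisq(q, df = 2 * k) / 2
      hit <- mean(null_draws <= closed)
      se <- sqrt(q * (1 - q) / 20000)
      expect_lt(abs(hit - q), 4 * se)
    }
  }
})

test_that("reporter analysis selects planted signal ratios and their metabolites", {
  model <- make_toy_model(6, 12, 20)
  ratios <- suppressMessages(build_ratio_gene_map(model))
  target <- ratios$ratio[which.max(ratios$n_genes)]
  cfg <- synthetic_config(seed = 21, signal_beta_a = 0.05,
                          signal_ratios = target)
  gs <- simulate_gene_stats(model, cfg)
  # rank transform runs over the whole supplied table, as with a real
  # transcriptome: pad the network genes with a uniform background
  background <- local({
    set.seed(77)
    data.frame(gene = sprintf("bg%03d", 1:500), p = runif(500),
               log2fc = 0, fdr = 1, stringsAsFactors = FALSE)
  })
  gene_stats <- rbind(gs$gene_stats, background)
  res <- suppressMessages(
    reporter_analysis(model, gene_stats, n_sim = 2000, seed = 5))
  expect_true(res$significant[res$ratio == target])
  mets <- select_reporter_metabolites(res)
  ab <- strsplit(target, "~", fixed = TRUE)[[1]]
  expect_true(all(ab %in% mets))

  # no significant ratios -> empty metabolite set
  none <- res
  none$p_hat <- 1
  expect_length(select_reporter_metabolites(none), 0)

  # overlapping significant ratios union their members
  fake <- data.frame(ratio = c("a~b", "b~c"), met_a = c("a", "b"),
                     met_b = c("b", "c"), p_hat = c(0.01, 0.01))
  expect_setequal(select_reporter_metabolites(fake), c("a", "b", "c"))
})
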