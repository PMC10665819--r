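test_that("concentration conversion follows the unit arithmetic", {
  expect_equal(convert_concentration(1, 0.28, 100, 14), 2)
  expect_equal(convert_concentration(0, 0.28, 100, 14), 0)
  # glycine-like molar mass, hand arithmetic: 2 * 0.28 * 75.07 / 20
  expect_equal(convert_concentration(2, 0.28, 75.07, 20), 2.10196)
  expect_error(convert_concentration(1, 0.28, 100, 0), "pellet")
  expect_error(convert_concentration(-1, 0.28, 100, 14), "non-negative")
})

test_that("PQN removes dilution and reproduces a hand-traced case", {
  m <- matrix(c(1, 2, 4,
                2, 4, 8,
                1, 4, 4), nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  tab <- data.frame(sample = c("s1", "s2", "s3"), group = "wildtype", m,
                    stringsAsFactors = FALSE)
  # integral-normalized rows: (1,2,4)/7, (1,2,4)/7, (1,4,4)/9
  # reference = column medians = (1/7, 2/7, 4/7)
  # quotients: s1, s2 -> (1,1,1), factor 1; s3 -> (7/9, 14/9, 7/9), factor 7/9
  out <- pqn_normalize(tab)
  expect_equal(unlist(out[1, c("a", "b", "c")]), c(a = 1, b = 2, c = 4) / 7,
               tolerance = 1e-12)
  expect_equal(unlist(out[2, c("a", "b", "c")]), c(a = 1, b = 2, c = 4) / 7,
               tolerance = 1e-12)
  expect_equal(unlist(out[3, c("a", "b", "c")]), c(a = 1, b = 4, c = 4) / 7,
               tolerance = 1e-12)

  # identical samples stay identical and keep their profile shape
  same <- tab
  same[, c("a", "b", "c")] <- matrix(rep(c(1, 2, 3), each = 3), nrow = 3)
  outs <- pqn_normalize(same)
  expect_equal(unlist(outs[1, c("a", "b", "c")]),
               c(a = 1, b = 2, c = 3) / 6, tolerance = 1e-12)
  expect_equal(outs[1, 3:5], outs[2, 3:5], ignore_attr = TRUE,
               tolerance = 1e-12)

  # a pure dilution of the reference sample is fully removed
  dil <- tab[1:2, ]
  dil[2, c("a", "b", "c")] <- 3 * dil[1, c("a", "b", "c")]
  outd <- pqn_normalize(dil, reference = "group:wildtype")
  expect_equal(unlist(outd[2, c("a", "b", "c")]),
               unlist(outd[1, c("a", "b", "c")]), tolerance = 1e-12)

  zero <- tab
  zero[2, c("a", "b", "c")] <- 0
  expect_error(pqn_normalize(zero), "s2")
})

test_that("PQN is idempotent and invariant to per-sample scaling", {
  for (seed in 1:5) {
    tab <- local({
      set.seed(seed)
      m <- matrix(10^runif(8 * 12, -2, 1), nrow = 8,
                  dimnames = list(NULL, sprintf("m%02d", 1:12)))
      data.frame(sample = sprintf("s%d", 1:8), group = "wildtype", m,
                 stringsAsFactors = FALSE)
    })
    once <- pqn_normalize(tab)
    twice <- pqn_normalize(once)
    expect_equal(twice, once, tolerance = 1e-10)

    set.seed(seed + 100)
    d <- 10^runif(8, -1, 1)
    scaled <- tab
    scaled[, 3:14] <- diag(d) %*% as.matrix(tab[, 3:14])
    expect_equal(pqn_normalize(scaled), once, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney exact branch matches the printed small cases", {
  r1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 0.1)
  expect_true(r1$exact)

  r2 <- mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 2 / 70)

  # identical groups: symmetric null, p = 1 (tied branch)
  r3 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r3$p, 1)
  expect_false(r3$exact)

  expect_error(mann_whitney(c(1, 2), c(3, 4, 5)), "at least 3")
})

test_that("Mann-Whitney exact branch equals full enumeration on random samples", {
  set.seed(42)
  for (i in 1:100) {
    m <- sample(3:5, 1)
    n <- sample(3:5, 1)
    vals <- sample(1000, m + n)  # distinct -> no ties
    a <- vals[seq_len(m)]
    b <- vals[-seq_len(m)]
    got <- mann_whitney(a, b)
    ora <- mw_enumeration_p(a, b)
    expect_true(got$exact)
    expect_equal(got$U, ora$U)
    expect_equal(got$p, ora$p, tolerance = 1e-12)
  }
})

test_that("univariate screen recovers an implanted shift and reports log2FC", {
  cfg <- synthetic_config(
    seed = 7, n_per_group = 200, metabolites = sprintf("met%02d", 1:10),
    metabolite_effects = list(met03 = list(group = "disease", shift = 2)))
  sim <- simulate_metabolite_table(cfg)
  res <- univariate_screen(sim$table, c("disease", "wildtype"))
  hit <- res[res$metabolite == "met03", ]
  expect_true(hit$significant)
  expect_equal(hit$log2fc, 1, tolerance = 0.15)
  expect_false(any(res$significant[res$p >= 0.05]))
})

test_that("univariate screen holds its nominal type-I error under the null", {
  flagged <- 0L
  total <- 0L
  for (seed in 1:12) {
    cfg <- synthetic_config(seed = seed, n_per_group = 8,
                            metabolites = sprintf("met%02d", 1:40))
    sim <- simulate_metabolite_table(cfg)
    res <- univariate_screen(sim$table, c("disease", "wildtype"))
    flagged <- flagged + sum(res$significant)
    total <- total + nrow(res)
  }
  rate <- flagged / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lt(abs(rate - 0.05), 3 * se + 1e-12)
})

test_that("PCA matches an independent eigendecomposition and its invariances", {
  m <- matrix(c(1, 2, 0.5,
                2, 4.1, 1,
                3, 5.9, 2,
                4, 8.2, 2.5), nrow = 4, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  tab <- data.frame(sample = sprintf("s%d", 1:4), group = "wildtype", m,
                    stringsAsFactors = FALSE)
  got <- pca_scores(tab, k = 3)
  ev <- eigen(stats::cor(m))$values   # autoscaled data -> correlation matrix
  expect_equal(got$explained, ev / sum(ev), tolerance = 1e-10)
  expect_true(all(diff(got$explained) <= 1e-12))
  expect_lte(sum(got$explained), 1 + 1e-12)

  # rank-1 data: two perfectly correlated metabolites
  r1 <- data.frame(sample = sprintf("s%d", 1:4), group = "g",
                   a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_equal(pca_scores(r1)$explained[1], 1, tolerance = 1e-12)

  # row permutation leaves explained variances unchanged
  perm <- tab[c(3, 1, 4, 2), ]
  expect_equal(pca_scores(perm)$explained, got$explained, tolerance = 1e-12)

  # constant column dropped with a warning
  cst <- tab
  cst$c <- 5
  expect_warning(res <- pca_scores(cst), "constant")
  expect_equal(length(res$explained), 2L)
})
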