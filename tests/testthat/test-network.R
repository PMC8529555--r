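test_that("expression filter removes genes strictly below the floor", {
  m <- tiny_expr(c(0.2, 0.2, 0.2,  1, 1, 1,  5, 5, 5),
                 c("low", "edge", "high"), paste0("s", 1:3))
  expect_message(f <- filter_low_expression(m, "median", 1), "removed 1")
  expect_identical(rownames(f), c("edge", "high"))   # median == 1 survives

  expect_identical(rownames(filter_low_expression(m, "median", 0)),
                   rownames(m))

  zeros <- tiny_expr(rep(0, 6), c("a", "b"), paste0("s", 1:3))
  expect_error(filter_low_expression(zeros, "median", 1), "no genes pass")
})

test_that("Spearman correlations hit monotone extremes and exact small-n p", {
  m <- tiny_expr(c(1, 2, 3, 4, 5,  10, 20, 30, 40, 50,  50, 40, 30, 20, 10),
                 c("a", "b", "c"), paste0("s", 1:5))
  pairs <- spearman_all_pairs(m)
  ab <- pairs[pairs$gene_a == "a" & pairs$gene_b == "b", ]
  ac <- pairs[pairs$gene_a == "a" & pairs$gene_b == "c", ]
  expect_equal(ab$rho, 1)
  expect_equal(ac$rho, -1)
  # n = 5, rho = 1: exact two-sided p = 2/5! * (number of extreme perms) = 2/120
  expect_equal(ab$p_value, 2 / 120, tolerance = 1e-12)

  # zero-variance gene: rho 0, p 1, warning
  mz <- tiny_expr(c(1, 2, 3, 4, 5, 7, 7, 7, 7, 7), c("a", "z"), paste0("s", 1:5))
  expect_warning(pz <- spearman_all_pairs(mz), "zero-variance")
  expect_equal(pz$rho, 0)
  expect_equal(pz$p_value, 1)
})

test_that("large-n Spearman matches cor.test per pair", {
  set.seed(5)
  m <- expr_matrix(matrix(2^rnorm(6 * 40, 4, 1), nrow = 6,
                          dimnames = list(letters[1:6], paste0("s", 1:40))), "tpm")
  pairs <- spearman_all_pairs(m)
  for (r in sample(nrow(pairs), 5)) {
    ct <- suppressWarnings(
      cor.test(unclass(m)[pairs$gene_a[r], ], unclass(m)[pairs$gene_b[r], ],
               method = "spearman", exact = FALSE))
    expect_equal(pairs$rho[r], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(pairs$p_value[r], ct$p.value, tolerance = 1e-8)
  }
  # identical results regardless of block size
  expect_equal(spearman_all_pairs(m, block_size = 2L), pairs)
})

test_that("network retains positive significant edges, never negative ones", {
  set.seed(7)
  n <- 20
  base <- rnorm(n)
  m <- rbind(
    pos1 = base + rnorm(n, 0, 1e-3),
    pos2 = base + rnorm(n, 0, 1e-3),
    neg1 = -base + rnorm(n, 0, 1e-3),
    matrix(rnorm(6 * n), nrow = 6,
           dimnames = list(paste0("noise", 1:6), NULL))
  )
  colnames(m) <- paste0("s", 1:n)
  expr <- expr_matrix(2^m, "tpm")
  cfg <- analysis_config(top_edge_fraction = 1)
  net <- build_network(expr, cfg)
  key <- paste(net$edges$gene_a, net$edges$gene_b)
  expect_true("pos1 pos2" %in% key)
  # the perfectly anti-correlated pairs can never enter the network
  expect_false(any(c("neg1 pos1", "neg1 pos2") %in% key))
  expect_true(all(net$edges$rho > 0))
  expect_true(all(net$edges$fdr < cfg$edge_fdr_alpha))
  # provenance counts all pairs
  expect_equal(net$provenance$n_pairs_tested, 9 * 8 / 2)
})

test_that("top-fraction retention count is exact and scale invariant", {
  set.seed(8)
  g <- 12; n <- 30
  f <- rnorm(n)
  m <- matrix(rep(f, each = g), nrow = g) * 0.8 + matrix(rnorm(g * n, 0, 0.6), g)
  dimnames(m) <- list(sprintf("g%02d", 1:g), paste0("s", 1:n))
  expr <- expr_matrix(2^m, "tpm")
  for (frac in c(0.1, 0.25, 1)) {
    cfg <- analysis_config(top_edge_fraction = frac)
    net <- build_network(expr, cfg)
    expect_identical(nrow(net$edges),
                     as.integer(ceiling(frac * net$provenance$n_significant_positive)))
  }
  # strictly increasing transform of one gene leaves the edge set unchanged
  net1 <- build_network(expr, analysis_config())
  m2 <- unclass(expr); m2["g03", ] <- m2["g03", ]^3 / 50
  net2 <- build_network(expr_matrix(m2, "tpm"), analysis_config())
  expect_equal(net1$edges[, c("gene_a", "gene_b")],
               net2$edges[, c("gene_a", "gene_b")])
})
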