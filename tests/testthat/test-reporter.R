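test_that("inverse-normal Z-scores clamp and centre correctly", {
  stats <- tibble::tibble(gene_id = c("a", "b", "c"),
                          p_value = c(0.5, 0.05, 1))
  z <- gene_zscores(stats)
  expect_equal(z$z[1], 0)
  expect_equal(z$z[2], qnorm(0.95), tolerance = 1e-4)   # 1.6449
  expect_equal(z$z[3], qnorm(1e-15), tolerance = 1e-4)  # ~ -7.94, finite
  expect_true(all(is.finite(z$z)))
  expect_error(gene_zscores(tibble::tibble(gene_id = "a", p_value = 0)),
               "p-values")
})

test_that("directional subsetting and module masking reset opposing p to 1", {
  stats <- tibble::tibble(
    gene_id = c("up1", "dn1", "flat"),
    log2fc = c(2, -2, 0),
    p_value = c(0.001, 0.001, 0.2),
    adj_p = c(0.01, 0.01, 0.5)
  )
  up <- directional_subset(stats, "up")
  expect_equal(up$p_value, c(0.001, 1, 1))   # zero log2fc opposes "up"
  dn <- directional_subset(stats, "down")
  expect_equal(dn$p_value, c(1, 0.001, 1))
  # mirror symmetry under sign flip
  flipped <- stats; flipped$log2fc <- -flipped$log2fc
  expect_equal(directional_subset(flipped, "down")$p_value, up$p_value)

  masked <- module_mask(stats, c("up1", "flat"))
  expect_equal(masked$p_value, c(0.001, 1, 0.2))
  expect_warning(module_mask(stats, "ghost"), "no module gene")
  expect_error(module_mask(stats, character(0)), "empty")
})

test_that("reporter aggregation follows the sum/sqrt(k) formula", {
  set.seed(1)
  null_p <- runif(20000)
  hit_p <- rep(pnorm(2, lower.tail = FALSE), 4)
  stats <- tibble::tibble(gene_id = c(sprintf("n%05d", 1:20000),
                                      paste0("hit", 1:4)),
                          p_value = c(null_p, hit_p))
  fm <- feature_map(tibble::tibble(
    feature_id = c(rep("F1", 4), "F2"),
    gene = c(paste0("hit", 1:4), "n00001")
  ))
  res <- reporter_scores(gene_zscores(stats), fm, n_background = 20000, seed = 3)
  f1 <- res[res$feature_id == "F1", ]
  expect_equal(f1$z_raw, 4, tolerance = 1e-9)       # 4 * 2 / sqrt(4)
  expect_equal(f1$z_corrected, 4, tolerance = 0.1)  # large null pool: mu~0, sd~1
  # k = 1 feature: z_raw is the gene's own z
  f2 <- res[res$feature_id == "F2", ]
  expect_equal(f2$z_raw, qnorm(1 - null_p[1]), tolerance = 1e-9)
})

test_that("identical p-values give centred scores; deviating degenerates error", {
  stats <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                          p_value = rep(0.2, 300))
  fm <- feature_map(tibble::tibble(
    feature_id = rep(paste0("F", 1:10), each = 5),
    gene = sprintf("g%03d", 1:50)
  ))
  res <- reporter_scores(gene_zscores(stats), fm, n_background = 500, seed = 2)
  expect_true(all(res$z_corrected == 0))
  expect_true(all(res$p_value == 0.5))
})

test_that("permutation invariance and skipped-feature accounting hold", {
  set.seed(6)
  stats <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                          p_value = runif(200))
  z <- gene_zscores(stats)
  fm1 <- feature_map(tibble::tibble(feature_id = "F", gene = c("g001", "g002", "g003")))
  fm2 <- feature_map(tibble::tibble(feature_id = "F", gene = c("g003", "g001", "g002")))
  r1 <- reporter_scores(z, fm1, n_background = 1000, seed = 4)
  r2 <- reporter_scores(z, fm2, n_background = 1000, seed = 4)
  expect_equal(r1$z_raw, r2$z_raw)
  expect_equal(r1$z_corrected, r2$z_corrected)

  fm3 <- feature_map(tibble::tibble(feature_id = c("F", "GONE"),
                                    gene = c("g001", "zz")))
  expect_message(r3 <- reporter_scores(z, fm3, n_background = 1000, seed = 4),
                 "skipped 1")
  expect_identical(r3$feature_id, "F")

  # determinism under seed
  r4 <- reporter_scores(z, fm1, n_background = 1000, seed = 4)
  expect_identical(r1, r4)
})
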