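test_that("jaccard index handles identity, disjoint sets and counts", {
  a <- paste0("g", 1:38)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, paste0("x", 1:10)), 0)
  expect_error(jaccard_index(a, character(0)), "non-empty")
  expect_equal(jaccard_index(c("a", "b", "a"), c("b", "c")), 1 / 3)  # dedup
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  # universe 10, |A| = 4, |B| = 5, overlap 3: enumeration gives 11/42
  a <- paste0("g", 1:4); b <- paste0("g", c(2, 3, 4, 9, 10))
  res <- overlap_test(a, b, paste0("g", 1:10))
  expect_equal(res$overlap_count, 3L)
  expect_equal(res$hyper_p, 11 / 42, tolerance = 1e-12)
  expect_equal(res$hyper_p, hyper_enum_oracle(10, 4, 5, 3), tolerance = 1e-12)

  # overlap 0 has probability 1 of being >= 0
  expect_equal(overlap_test("g1", "g2", 10)$hyper_p, 1)
  # |A| = universe forces full overlap, p = 1
  u <- paste0("g", 1:6)
  expect_equal(overlap_test(u, u[1:3], u)$hyper_p, 1)
  expect_error(overlap_test(c("g1", "zz"), "g2", paste0("g", 1:5)), "zz")

  # monotone: p non-increasing in observed overlap at fixed margins
  p_at_k <- vapply(0:4, function(k) {
    phyper(k - 1, 4, 8, 5, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(p_at_k) <= 0))
})

test_that("cross-cohort conservation scores every module pair", {
  p1 <- structure(list(cohort_id = "c1",
                       modules = list(`1` = paste0("g", 1:40),
                                      `2` = paste0("g", 41:75)),
                       unassigned = paste0("g", 76:100)),
                  class = "module_partition")
  p2 <- structure(list(cohort_id = "c2",
                       modules = list(`1` = paste0("g", 1:40),
                                      `2` = paste0("g", 41:75)),
                       unassigned = paste0("g", 76:100)),
                  class = "module_partition")
  cons <- all_pairs_conservation(list(p1, p2))
  expect_identical(nrow(cons), 4L)   # 2 x 2 module pairs
  diag_rows <- cons[cons$module_a == cons$module_b, ]
  expect_true(all(diag_rows$jaccard == 1))
  expect_true(all(diag_rows$significant))

  # identical single-module cohorts give one consensus module = the module
  q1 <- structure(list(cohort_id = "c1", modules = list(`1` = paste0("g", 1:40)),
                       unassigned = paste0("g", 41:80)), class = "module_partition")
  q2 <- structure(list(cohort_id = "c2", modules = list(`1` = paste0("g", 1:40)),
                       unassigned = paste0("g", 41:80)), class = "module_partition")
  cc <- all_pairs_conservation(list(q1, q2))
  cm <- extract_consensus(cc, list(q1, q2))
  expect_identical(nrow(cm), 1L)
  expect_identical(cm$consensus_genes[[1]], sort(paste0("g", 1:40)))

  # no significant pairs -> empty consensus list
  r1 <- structure(list(cohort_id = "c1", modules = list(`1` = paste0("g", 1:5)),
                       unassigned = paste0("g", 6:100)), class = "module_partition")
  r2 <- structure(list(cohort_id = "c2", modules = list(`1` = paste0("g", 96:100)),
                       unassigned = paste0("g", 1:95)), class = "module_partition")
  rc <- all_pairs_conservation(list(r1, r2))
  expect_identical(nrow(extract_consensus(rc, list(r1, r2))), 0L)

  # disjoint gene namespaces are an error under the intersection policy
  s2 <- structure(list(cohort_id = "c2", modules = list(`1` = paste0("x", 1:40)),
                       unassigned = character(0)), class = "module_partition")
  expect_error(all_pairs_conservation(list(q1, s2)), "share no genes")
})

test_that("overlap p-values agree with enumeration over a grid of margins", {
  for (u in c(6, 9, 12)) {
    for (a in c(2, u %/% 2)) {
      for (b in c(3, u - 2)) {
        for (k in unique(c(0, 1, min(a, b)))) {
          if (k > min(a, b) || b > u) next
          expect_equal(
            phyper(k - 1, a, u - a, b, lower.tail = FALSE),
            hyper_enum_oracle(u, a, b, k),
            tolerance = 1e-10
          )
        }
      }
    }
  }
})
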