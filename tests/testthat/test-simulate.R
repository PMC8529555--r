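test_that("generators are deterministic under the design seed", {
  d <- synthetic_design(samples_per_cohort = c(40, 40, 40), seed = 7L)
  s1 <- generate_cohorts(d)
  s2 <- generate_cohorts(d)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$metadata, s2$metadata)

  f1 <- generate_feature_map(d)
  f2 <- generate_feature_map(d)
  expect_identical(f1, f2)

  v1 <- generate_survival(s1$expr[[1]], d)
  v2 <- generate_survival(s1$expr[[1]], d)
  expect_identical(v1, v2)

  # a different seed changes the data
  d2 <- synthetic_design(samples_per_cohort = c(40, 40, 40), seed = 8L)
  expect_false(identical(generate_cohorts(d2)$expr, s1$expr))
})

test_that("design validation rejects inconsistent settings", {
  expect_error(synthetic_design(n_cohorts = 5), "2-4")
  expect_error(synthetic_design(samples_per_cohort = c(50, 50)), "entry per cohort")
  expect_error(synthetic_design(group_proportions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(synthetic_design(loading = 1.5), "loading")
  expect_error(synthetic_design(de_effects = c(control = 1, NAFL = 1, NASH = 1)),
               "reference")
  expect_error(synthetic_design(tf_targets_per_feature = 10000), "universe")
  expect_error(synthetic_design(surv_coefficients = c(ghost = 1)), "outside")
})

test_that("planted modules are internally correlated above background", {
  d <- synthetic_design(seed = 11L)
  sim <- generate_cohorts(d)
  m <- log2(unclass(sim$expr[[1]]) + 1)
  dis <- d$genes$disease[1:20]
  bg <- d$genes$background[1:20]
  c_within <- cor(t(m[dis, ]), method = "spearman")
  c_cross <- cor(t(m[dis, ]), t(m[bg, ]), method = "spearman")
  mean_within <- mean(c_within[upper.tri(c_within)])
  expect_gte(mean_within - mean(c_cross), 0.3)
})

test_that("realised disease-module fold changes track the design effect", {
  d <- synthetic_design(samples_per_cohort = c(150, 60, 60), seed = 13L)
  sim <- generate_cohorts(d)
  md <- sim$metadata[sim$metadata$cohort_id == "cohort1", ]
  m <- unclass(sim$expr[[1]])
  ctrl <- md$sample_id[md$group_label == "control"]
  nafl <- md$sample_id[md$group_label == "NAFL"]
  lfc <- log2((rowMeans(m[d$genes$disease, nafl]) + 1) /
                (rowMeans(m[d$genes$disease, ctrl]) + 1))
  expect_lt(abs(mean(lfc) - 1), 0.15)
})

test_that("feature maps concentrate targets as designed", {
  # concentration 1: every feature's targets inside the disease module
  d1 <- synthetic_design(tf_concentrated_fraction = 1, seed = 17L)
  fm1 <- generate_feature_map(d1)
  expect_true(all(fm1$gene %in% d1$genes$disease))

  # concentration 0: overlap with the disease module near its share of
  # the universe
  d0 <- synthetic_design(tf_concentrated_fraction = 0, seed = 17L)
  fm0 <- generate_feature_map(d0)
  n_universe <- length(c(d0$genes$disease, unlist(d0$genes$specific),
                         d0$genes$background, d0$genes$low))
  expected <- length(d0$genes$disease) / n_universe
  observed <- mean(fm0$gene %in% d0$genes$disease)
  se <- sqrt(expected * (1 - expected) / nrow(fm0))
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("survival generator ties hazard to the designated genes", {
  d <- synthetic_design(samples_per_cohort = c(200, 40, 40), seed = 19L)
  sim <- generate_cohorts(d)
  surv <- generate_survival(sim$expr[[1]], d)
  expect_true(all(surv$time > 0))
  expect_true(all(surv$event %in% c(0L, 1L)))
  # the +1 coefficient gene: high expressors die faster
  g <- names(d$surv_coefficients)[1]
  x <- unclass(sim$expr[[1]])[g, ]
  hi <- surv[x > median(x), ]; lo <- surv[x <= median(x), ]
  res <- logrank_test(hi, lo)
  expect_gt(res$observed_high, res$expected_high)
  expect_lt(res$p_value, 0.05)

  bad <- synthetic_design(seed = 19L,
                          surv_coefficients = c(DIS_g001 = 1))
  expect_error(generate_survival(sim$expr[[1]][11:20, ], bad, seed = 1),
               "not in matrix")
})

test_that("a zero-coefficient hazard is calibrated at a fixed median split", {
  d <- synthetic_design(surv_coefficients = c(DIS_g001 = 0), seed = 29L)
  set.seed(402)
  n <- 200
  m <- matrix(2^rnorm(200 * n, 5, 1), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:n)))
  m <- rbind(m, DIS_g001 = 2^rnorm(n, 5, 1))
  expr <- expr_matrix(m, "tpm")
  surv <- generate_survival(expr, d, seed = 55)
  ps <- vapply(1:200, function(i) {
    x <- unclass(expr)[i, ]
    hi <- surv[x > median(x), ]; lo <- surv[x <= median(x), ]
    logrank_test(hi, lo)$p_value
  }, numeric(1))
  frac <- mean(ps < 0.05)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("simulate_study writes a complete, readable fixture set", {
  dir <- withr::local_tempdir()
  d <- synthetic_design(samples_per_cohort = c(30, 30), n_cohorts = 2,
                        seed = 23L)
  paths <- suppressMessages(simulate_study(d, dir))
  expect_true(all(file.exists(unlist(paths))))
  back <- read_expression_tsv(paths$expr_cohort1)
  expect_identical(dim(back), dim(generate_cohorts(d)$expr[[1]]))
  gmt <- read_gmt(paths$gmt)
  expect_true("disease_module" %in% gmt$set_id)
  tf <- read_tf_targets(paths$tf_targets)
  expect_s3_class(tf, "feature_map")
  surv <- suppressMessages(read_survival_table(paths$survival))
  expect_identical(nrow(surv), 30L)
})
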