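test_that("product-limit estimates match hand computation", {
  # no events: flat at 1
  s <- tibble::tibble(sample_id = letters[1:3], time = c(1, 2, 3),
                      event = c(0L, 0L, 0L))
  expect_true(all(km_estimate(s)$surv == 1))

  # event, censor, event, censor: S(1) = 3/4, S(2) = 3/8
  s <- tibble::tibble(sample_id = letters[1:4], time = c(1, 1.5, 2, 3),
                      event = c(1L, 0L, 1L, 0L))
  km <- km_estimate(s)
  expect_equal(km_survival_at(km, 1), 3 / 4)
  expect_equal(km_survival_at(km, 2), 0.375)

  # single subject with event: S drops to 0
  s1 <- tibble::tibble(sample_id = "a", time = 5, event = 1L)
  expect_equal(km_survival_at(km_estimate(s1), 5), 0)
  expect_error(km_estimate(s1[0, ]), "empty")
})

test_that("KM curves equal the hand product-limit on all small patterns", {
  for (n in 1:6) {
    for (code in 0:(2^n - 1)) {
      event <- as.integer(intToBits(code))[1:n]
      time <- seq_len(n)
      s <- tibble::tibble(sample_id = paste0("p", 1:n), time = time,
                          event = event)
      km <- km_estimate(s)
      oracle <- km_hand_oracle(time, event)
      expect_equal(km$time, oracle$time)
      expect_equal(km$surv, oracle$surv, tolerance = 1e-12)
    }
  }
  # tied event/censor times
  s <- tibble::tibble(sample_id = paste0("p", 1:6),
                      time = c(1, 1, 2, 2, 2, 3),
                      event = c(1L, 1L, 1L, 0L, 1L, 0L))
  km <- km_estimate(s)
  oracle <- km_hand_oracle(s$time, s$event)
  expect_equal(km$surv, oracle$surv, tolerance = 1e-12)
})

test_that("log-rank expectations come from risk-set accumulation", {
  hi <- tibble::tibble(sample_id = c("a", "b"), time = c(1, 2), event = c(1L, 1L))
  lo <- tibble::tibble(sample_id = c("c", "d"), time = c(3, 4), event = c(1L, 1L))
  res <- logrank_test(hi, lo)
  # E_high = 1*(2/4) + 1*(1/3): after the t=1 death only one high subject
  # remains at risk at t=2
  expect_equal(res$expected_high, 2 / 4 + 1 / 3, tolerance = 1e-12)
  expect_equal(res$observed_high, 2)
  # survdiff is the independent oracle
  sd1 <- survival::survdiff(
    survival::Surv(c(1, 2, 3, 4), rep(1, 4)) ~ c(1, 1, 0, 0))
  expect_equal(res$chi2, sd1$chisq, tolerance = 1e-10)
  expect_equal(res$expected_high, sd1$exp[[2]], tolerance = 1e-10)

  # identical groups: chi2 = 0, p = 1
  same <- tibble::tibble(sample_id = c("x", "y"), time = c(2, 5),
                         event = c(1L, 0L))
  same2 <- same; same2$sample_id <- c("u", "v")
  res0 <- logrank_test(same, same2)
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p_value, 1)

  # label-swap symmetry
  swap <- logrank_test(lo, hi)
  expect_equal(swap$chi2, res$chi2)
  expect_equal(swap$p_value, res$p_value)

  expect_error(logrank_test(hi[0, ], lo), "non-empty")
  nohits <- tibble::tibble(sample_id = "q", time = 3, event = 0L)
  expect_error(logrank_test(nohits, nohits), "no events")
})

test_that("log-rank matches survdiff across random instances", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    time <- round(rexp(n, 0.1), 2) + 0.01
    event <- rbinom(n, 1, 0.7)
    grp <- rbinom(n, 1, 0.5)
    if (sum(event) == 0 || length(unique(grp)) < 2) next
    hi <- tibble::tibble(sample_id = paste0("h", which(grp == 1)),
                         time = time[grp == 1], event = as.integer(event[grp == 1]))
    lo <- tibble::tibble(sample_id = paste0("l", which(grp == 0)),
                         time = time[grp == 0], event = as.integer(event[grp == 0]))
    mine <- logrank_test(hi, lo)
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(mine$chi2, ref$chisq, tolerance = 1e-9)
  }
})

test_that("null relabelling produces approximately uniform log-rank p", {
  set.seed(15)
  n <- 60
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.8)
  ps <- vapply(1:200, function(i) {
    grp <- sample(rep(c(TRUE, FALSE), n / 2))
    coexmod:::logrank_core(time, event, grp)$p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.12)
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.08)
})

test_that("cutoff scan selects the minimum-p cutpoint within the band", {
  set.seed(17)
  n <- 120
  x <- setNames(2^rnorm(n, 4, 1), paste0("s", 1:n))
  risk <- scale(log2(x + 1))[, 1]
  time <- rexp(n, 0.01 * exp(risk))
  cens <- rexp(n, 0.005)
  surv <- tibble::tibble(sample_id = names(x), time = pmin(time, cens),
                         event = as.integer(time <= cens))
  cfg <- analysis_config()
  res <- cutoff_scan(x, surv, cfg)
  band <- quantile(x, cfg$surv_percentile_band / 100)
  expect_gte(res$best_cutoff_value, band[[1]])
  expect_lte(res$best_cutoff_value, band[[2]])
  expect_equal(res$n_high + res$n_low, n)
  # minimum property: selected p <= p at the median cutoff
  med_cut <- median(x)
  at_med <- coexmod:::logrank_core(surv$time, surv$event, x > med_cut)
  expect_lte(res$logrank_p, at_med$p + 1e-12)
  # planted positive hazard: unfavourable call
  expect_identical(res$direction, "unfavourable")

  expect_error(cutoff_scan(setNames(rep(2, n), names(x)), surv, cfg),
               "constant")
})

test_that("batch prognosis filters by mean TPM and stays deterministic", {
  set.seed(19)
  n <- 80
  m <- rbind(
    hi1 = 2^rnorm(n, 5, 1),
    hi2 = 2^rnorm(n, 5, 1),
    dim = rep(0.5, n) + runif(n, 0, 0.1)
  )
  colnames(m) <- paste0("s", 1:n)
  expr <- expr_matrix(m, "tpm")
  surv <- tibble::tibble(sample_id = colnames(m),
                         time = rexp(n, 0.01), event = rbinom(n, 1, 0.7))
  expect_message(res <- batch_prognosis(expr, surv, analysis_config()),
                 "excluded 1")
  expect_setequal(res$gene_id, c("hi1", "hi2"))
  res2 <- suppressMessages(batch_prognosis(expr, surv, analysis_config()))
  expect_identical(res, res2, ignore_attr = TRUE)
})
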