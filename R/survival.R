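#' Kaplan-Meier product-limit estimate
#'
#' Computed with [survival::survfit()]; censored subjects leave the risk set
#' after their censoring time, so the curve starts at 1 and is
#' non-increasing.
#'
#' @param surv Survival tibble (`sample_id`, `time`, `event`) with all
#'   times > 0.
#' @return A `km_estimate`: list with `time` (distinct event/censor times),
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(surv) {
  if (nrow(surv) == 0) stop("empty survival table", call. = FALSE)
  if (any(surv$time <= 0)) stop("survival times must be positive", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(surv))
  structure(list(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    n = nrow(surv)
  ), class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> n = %d, %d event(s); final S(t) = %.3f\n",
              x$n, sum(x$n_event), utils::tail(x$surv, 1)))
  invisible(x)
}

#' @describeIn km_estimate Tidy the curve into a tibble.
#' @param x A `km_estimate`.
#' @param ... Unused.
#' @method tidy km_estimate
#' @export
tidy.km_estimate <- function(x, ...) {
  tibble::tibble(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                 n_censor = x$n_censor, surv = x$surv)
}

#' @describeIn km_estimate One-row summary.
#' @method glance km_estimate
#' @export
glance.km_estimate <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = sum(x$n_event),
                 final_surv = utils::tail(x$surv, 1))
}

#' Survival probability at a time point
#' @param km A `km_estimate`.
#' @param t Time.
#' @return S(t), the estimated survival probability just after `t`.
#' @export
km_survival_at <- function(km, t) {
  idx <- which(km$time <= t)
  if (length(idx) == 0) return(1)
  km$surv[max(idx)]
}

#' Two-group log-rank test
#'
#' At each distinct event time the expected number of events in the high
#' group is proportional to its share of the risk set; the statistic is
#' `(O - E)^2 / V` with the hypergeometric variance, referred to a
#' chi-square with 1 d.f. The observed and expected event counts of the
#' high group are returned so callers can classify prognosis direction.
#'
#' @param high,low Survival tibbles for the two groups.
#' @return A one-row tibble: `chi2`, `p_value`, `observed_high`,
#'   `expected_high`, `n_high`, `n_low`.
#' @export
logrank_test <- function(high, low) {
  if (nrow(high) == 0 || nrow(low) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  res <- logrank_core(c(high$time, low$time), c(high$event, low$event),
                      rep(c(TRUE, FALSE), c(nrow(high), nrow(low))))
  tibble::tibble(chi2 = res$chi2, p_value = res$p,
                 observed_high = res$o_high, expected_high = res$e_high,
                 n_high = nrow(high), n_low = nrow(low))
}

# Core log-rank computation on vectors; `high` is a logical group indicator.
# Risk sets are accumulated over distinct times via cumulative counts so a
# single call is O(n log n), which keeps the per-cutoff scan cheap.
logrank_core <- function(time, event, high) {
  if (sum(event) == 0) stop("no events observed", call. = FALSE)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; h_s <- high[ord]
  ut <- unique(t_s)
  idx <- match(t_s, ut)
  cnt <- tabulate(idx, nbins = length(ut))
  cnt_h <- tabulate(idx[h_s], nbins = length(ut))
  n_at_risk <- length(t_s) - c(0, cumsum(cnt))[seq_along(ut)]
  n1_at_risk <- sum(h_s) - c(0, cumsum(cnt_h))[seq_along(ut)]
  d <- as.vector(rowsum(e_s, idx))
  d1 <- as.vector(rowsum(as.numeric(e_s * h_s), idx))
  keep <- d > 0
  n_j <- n_at_risk[keep]; n1_j <- n1_at_risk[keep]
  d_j <- d[keep]; d1_j <- d1[keep]
  o_high <- sum(d1_j)
  e_high <- sum(d_j * n1_j / n_j)
  vok <- n_j > 1
  v <- sum(d_j[vok] * (n1_j[vok] / n_j[vok]) * (1 - n1_j[vok] / n_j[vok]) *
             (n_j[vok] - d_j[vok]) / (n_j[vok] - 1))
  if (v <= 0) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- (o_high - e_high)^2 / v
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(chi2 = chi2, p = p, o_high = o_high, e_high = e_high)
}

#' Optimal-cutpoint survival scan for one gene
#'
#' Every distinct expression value inside the configured percentile band
#' (20th-80th by default) is tried as a cutpoint: samples strictly above it
#' form the high-expression group, the rest the low group, and the two are
#' compared by log-rank. The cutpoint with the smallest p-value wins (ties
#' broken toward the value nearest the median); the gene is `prognostic`
#' when that p-value is below `surv_alpha`, and `unfavourable` when the
#' high group shows more observed than expected events, `favourable`
#' otherwise. No multiple-testing correction is applied across cutpoints
#' or genes, so the selected p-values are optimistically biased — see the
#' package documentation.
#'
#' @param expression Named numeric vector (names = sample ids) of one
#'   gene's expression.
#' @param surv Survival tibble; only samples present in both inputs are
#'   used.
#' @param config An [analysis_config]; uses `surv_percentile_band` and
#'   `surv_alpha`.
#' @return A one-row tibble: `best_cutoff_value`, `best_cutoff_percentile`,
#'   `logrank_chi2`, `logrank_p`, `prognostic`, `direction`, `n_high`,
#'   `n_low`.
#' @export
cutoff_scan <- function(expression, surv, config = analysis_config()) {
  common <- intersect(names(expression), surv$sample_id)
  if (length(common) < 4) stop("need at least 4 aligned samples", call. = FALSE)
  x <- expression[common]
  st <- surv[match(common, surv$sample_id), ]
  if (length(unique(x)) == 1) stop("no valid cutoff: constant expression", call. = FALSE)
  band <- quantile(x, config$surv_percentile_band / 100, type = 7)
  cand <- sort(unique(x[x >= band[1] & x <= band[2]]))
  cand <- cand[cand < max(x)]          # a cutoff must leave a non-empty high group
  if (length(cand) < 2) stop("fewer than 2 candidate cutoffs in the band", call. = FALSE)
  res <- purrr::map(cand, function(cut) {
    hi <- x > cut
    out <- tryCatch(logrank_core(st$time, st$event, hi), error = function(e) NULL)
    if (is.null(out)) return(NULL)
    tibble::tibble(cutoff = cut, chi2 = out$chi2, p = out$p,
                   o_high = out$o_high, e_high = out$e_high,
                   n_high = sum(hi), n_low = sum(!hi))
  })
  res <- dplyr::bind_rows(purrr::compact(res))
  if (nrow(res) == 0) stop("no valid cutoff admitted a log-rank test", call. = FALSE)
  med <- median(x)
  best <- res[order(res$p, abs(res$cutoff - med), res$cutoff), ][1, ]
  ecdf_pos <- mean(x <= best$cutoff) * 100
  tibble::tibble(
    best_cutoff_value = best$cutoff,
    best_cutoff_percentile = ecdf_pos,
    logrank_chi2 = best$chi2,
    logrank_p = best$p,
    prognostic = best$p < config$surv_alpha,
    direction = ifelse(best$o_high > best$e_high, "unfavourable", "favourable"),
    n_high = best$n_high,
    n_low = best$n_low
  )
}

#' Batch prognosis scan over an expression matrix
#'
#' Runs [cutoff_scan()] for every gene passing the mean-TPM floor
#' (`surv_mean_tpm_min`, computed over the samples shared with the survival
#' table); genes whose scan fails are skipped with a count. Attributes
#' `n_filtered` and `n_failed` record the bookkeeping.
#'
#' @param expr An [expr_matrix] on TPM scale.
#' @param surv Survival tibble.
#' @param config An [analysis_config].
#' @return A tibble with one row per scanned gene (columns of
#'   [cutoff_scan()] plus `gene_id`), sorted by `logrank_p`.
#' @export
batch_prognosis <- function(expr, surv, config = analysis_config()) {
  stopifnot(is_expr_matrix(expr))
  common <- intersect(colnames(expr), surv$sample_id)
  if (length(common) < 4) stop("need at least 4 aligned samples", call. = FALSE)
  m <- unclass(expr)[, common, drop = FALSE]
  pass <- rowMeans(m) > config$surv_mean_tpm_min
  if (sum(!pass) > 0) {
    message(sprintf("excluded %d gene(s) with mean TPM <= %g",
                    sum(!pass), config$surv_mean_tpm_min))
  }
  genes <- rownames(m)[pass]
  n_failed <- 0
  rows <- purrr::map(genes, function(g) {
    out <- tryCatch(cutoff_scan(m[g, ], surv, config), error = function(e) NULL)
    if (is.null(out)) { n_failed <<- n_failed + 1; return(NULL) }
    dplyr::bind_cols(tibble::tibble(gene_id = g), out)
  })
  if (n_failed > 0) message(sprintf("skipped %d gene(s) whose scan failed", n_failed))
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) > 0) out <- out[order(out$logrank_p), ]
  attr(out, "n_filtered") <- sum(!pass)
  attr(out, "n_failed") <- n_failed
  out
}
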