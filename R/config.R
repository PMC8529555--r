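#' Analysis configuration
#'
#' Collects every numeric threshold the pipeline uses, with the defaults the
#' analysis is designed around: genes with median TPM < 1 are dropped before
#' correlation, edges must reach FDR < 0.05 and only the top 10% of
#' significant positive correlations are kept, modules under 30 genes are
#' discarded, differential expression calls use adjusted p < 0.01, module
#' overlaps and enrichments use 0.05, reporter backgrounds use 10,000 sampled
#' gene sets, and the survival cutpoint scan walks the 20th-80th expression
#' percentiles keeping genes with mean TPM > 1.
#'
#' @param tpm_filter_threshold Expression floor (TPM); genes whose summary
#'   statistic falls strictly below it are removed.
#' @param tpm_filter_stat Summary used by the expression filter, `"median"`
#'   (default) or `"mean"`.
#' @param edge_fdr_alpha FDR level for correlation edges.
#' @param top_edge_fraction Fraction of significant positive edges retained,
#'   in (0, 1].
#' @param min_module_size Modules with fewer genes are moved to unassigned.
#' @param deg_alpha Adjusted-p threshold for calling a gene differentially
#'   expressed.
#' @param overlap_alpha Significance level for module-overlap hypergeometric
#'   tests.
#' @param enrich_q_alpha BH q-value threshold for enrichment calls.
#' @param reporter_background_samples Number of random gene sets drawn per
#'   set size when standardising reporter scores.
#' @param reporter_alpha Significance level for reporter features.
#' @param surv_percentile_band Length-2 numeric, the percentile window
#'   scanned for survival cutpoints.
#' @param surv_alpha Log-rank p threshold for calling a gene prognostic.
#' @param surv_mean_tpm_min Mean-TPM floor for genes entering the survival
#'   scan.
#' @param rng_seed Integer seed controlling every stochastic step.
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(tpm_filter_threshold = 1,
                            tpm_filter_stat = c("median", "mean"),
                            edge_fdr_alpha = 0.05,
                            top_edge_fraction = 0.10,
                            min_module_size = 30,
                            deg_alpha = 0.01,
                            overlap_alpha = 0.05,
                            enrich_q_alpha = 0.05,
                            reporter_background_samples = 10000,
                            reporter_alpha = 0.05,
                            surv_percentile_band = c(20, 80),
                            surv_alpha = 0.05,
                            surv_mean_tpm_min = 1,
                            rng_seed = 1L) {
  tpm_filter_stat <- match.arg(tpm_filter_stat)
  cfg <- list(
    tpm_filter_threshold = tpm_filter_threshold,
    tpm_filter_stat = tpm_filter_stat,
    edge_fdr_alpha = edge_fdr_alpha,
    top_edge_fraction = top_edge_fraction,
    min_module_size = as.integer(min_module_size),
    deg_alpha = deg_alpha,
    overlap_alpha = overlap_alpha,
    enrich_q_alpha = enrich_q_alpha,
    reporter_background_samples = as.integer(reporter_background_samples),
    reporter_alpha = reporter_alpha,
    surv_percentile_band = as.numeric(surv_percentile_band),
    surv_alpha = surv_alpha,
    surv_mean_tpm_min = surv_mean_tpm_min,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  alphas <- c("edge_fdr_alpha", "deg_alpha", "overlap_alpha",
              "enrich_q_alpha", "reporter_alpha", "surv_alpha")
  for (a in alphas) {
    v <- cfg[[a]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1) {
      stop(sprintf("`%s` must be a single value in (0, 1)", a), call. = FALSE)
    }
  }
  if (cfg$top_edge_fraction <= 0 || cfg$top_edge_fraction > 1) {
    stop("`top_edge_fraction` must lie in (0, 1]", call. = FALSE)
  }
  band <- cfg$surv_percentile_band
  if (length(band) != 2 || band[1] >= band[2] || band[1] <= 0 || band[2] >= 100) {
    stop("`surv_percentile_band` must be an ordered pair within (0, 100)",
         call. = FALSE)
  }
  if (cfg$min_module_size < 1) stop("`min_module_size` must be >= 1", call. = FALSE)
  if (cfg$reporter_background_samples < 100) {
    stop("`reporter_background_samples` must be at least 100", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

# stable per-stage sub-seed so stages can be re-run in isolation
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
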