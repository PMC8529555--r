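#' Gene-level Z-scores from DE p-values
#'
#' Inverse-normal transform `z = qnorm(1 - p)` with p clamped to
#' `[1e-15, 1 - 1e-15]` so the result stays finite; `p = 0.5` maps to 0.
#'
#' @param stats Gene statistics tibble with `gene_id` and `p_value`.
#' @return A tibble with columns `gene_id`, `z`.
#' @export
gene_zscores <- function(stats) {
  p <- stats$p_value
  if (any(is.na(p)) || any(p <= 0)) {
    stop("p-values must be in (0, 1]", call. = FALSE)
  }
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  tibble::tibble(gene_id = stats$gene_id, z = qnorm(pc, lower.tail = FALSE))
}

#' Directional subset of a DE table
#'
#' Keeps the full gene list but neutralises genes whose fold change opposes
#' the requested direction by resetting their p-value to 1 (so their
#' Z-score collapses to the minimum). Running the reporter analysis once per
#' direction yields separate "up" and "down" reporter lists.
#'
#' @param stats Gene statistics tibble (`gene_id`, `log2fc`, `p_value`, ...).
#' @param direction `"up"` or `"down"`.
#' @return The tibble with opposing genes' p-values set to 1.
#' @export
directional_subset <- function(stats, direction = c("up", "down")) {
  direction <- match.arg(direction)
  opposes <- if (direction == "up") stats$log2fc <= 0 else stats$log2fc >= 0
  stats$p_value[opposes] <- 1
  stats
}

#' Mask a DE table to one module
#'
#' Genes outside the module get p = 1 so they contribute nothing to reporter
#' scores, eliminating influence from genes in other modules; genes inside
#' keep their p-values.
#'
#' @param stats Gene statistics tibble.
#' @param module_genes Non-empty character vector of module gene ids.
#' @return The masked tibble.
#' @export
module_mask <- function(stats, module_genes) {
  if (length(module_genes) == 0) stop("module is empty", call. = FALSE)
  inside <- stats$gene_id %in% module_genes
  if (!any(inside)) {
    warning("no module gene present in the statistics table; all p set to 1",
            call. = FALSE)
  }
  stats$p_value[!inside] <- 1
  stats
}

#' Reporter feature scores
#'
#' Scores each bipartite feature (metabolite or transcription factor) by
#' aggregating the Z-scores of its neighbour genes: for a feature with k
#' scored genes, `z_raw = sum(z_i) / sqrt(k)`. The raw score is standardised
#' against a sampled background — for every occurring k, `n_background`
#' random k-subsets of all scored genes are drawn and their `z_raw` mean and
#' s.d. give `z_corrected = (z_raw - mu_k) / sigma_k` — and converted to
#' `p = 1 - pnorm(z_corrected)`. Background moments are cached per k and the
#' whole computation is deterministic under `seed`. Features with no scored
#' genes are skipped (count reported).
#'
#' @param zscores Tibble from [gene_zscores()].
#' @param fmap A `feature_map` linking features to genes.
#' @param n_background Random subsets per distinct k (default 10,000).
#' @param seed Integer seed for the background sampler.
#' @param direction_context,module_context Labels recorded per row
#'   (`"all"`/`"up"`/`"down"`, and a module id or `NA`).
#' @return A tibble sorted by p: `feature_id`, `k`, `z_raw`, `z_corrected`,
#'   `p_value`, `direction_context`, `module_context`.
#' @export
reporter_scores <- function(zscores, fmap, n_background = 10000, seed = 1L,
                            direction_context = "all",
                            module_context = NA_character_) {
  z <- setNames(zscores$z, zscores$gene_id)
  links <- fmap[fmap$gene %in% names(z), c("feature_id", "gene")]
  n_skipped <- length(setdiff(unique(fmap$feature_id), unique(links$feature_id)))
  if (n_skipped > 0) {
    message(sprintf("skipped %d feature(s) with no scored genes", n_skipped))
  }
  if (nrow(links) == 0) stop("no feature has scored neighbour genes", call. = FALSE)
  neigh <- split(links$gene, links$feature_id)
  k_vals <- lengths(neigh)
  z_raw <- vapply(neigh, function(g) sum(z[g]) / sqrt(length(g)), numeric(1))

  moments <- background_moments(z, sort(unique(k_vals)), n_background, seed)
  mu <- moments$mu[as.character(k_vals)]
  sigma <- moments$sigma[as.character(k_vals)]
  # a degenerate background (all aggregates equal) is only tolerable when the
  # feature sits exactly at the background mean: the score is then central
  degen <- sigma == 0
  bad <- degen & abs(z_raw - mu) > 1e-8
  if (any(bad)) {
    stop("degenerate background (sd = 0) for k = ",
         paste(unique(k_vals[bad]), collapse = ", "), call. = FALSE)
  }
  z_corr <- ifelse(degen, 0, (z_raw - mu) / pmax(sigma, .Machine$double.xmin))
  p <- pnorm(z_corr, lower.tail = FALSE)
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  out <- tibble::tibble(
    feature_id = names(neigh),
    k = as.integer(k_vals),
    z_raw = unname(z_raw),
    z_corrected = unname(z_corr),
    p_value = unname(p),
    direction_context = direction_context,
    module_context = module_context
  )
  out[order(out$p_value, out$feature_id), ]
}

# Monte-Carlo background moments of z_raw for each subset size k, sampling
# k-subsets (without replacement) from the pool of scored-gene Z-scores.
background_moments <- function(z, ks, n_background, seed) {
  mu <- numeric(length(ks)); sigma <- numeric(length(ks))
  names(mu) <- names(sigma) <- as.character(ks)
  n <- length(z)
  with_seed(seed, {
    for (i in seq_along(ks)) {
      k <- ks[i]
      if (k > n) stop("feature has more neighbours than scored genes", call. = FALSE)
      draws <- vapply(seq_len(n_background), function(j) {
        sum(z[sample.int(n, k)]) / sqrt(k)
      }, numeric(1))
      mu[i] <- mean(draws)
      sigma[i] <- sd(draws)
    }
  })
  list(mu = mu, sigma = sigma)
}

#' Reporter transcription factors for one module
#'
#' Convenience wrapper mirroring the validation procedure for module-level
#' regulators: the DE table is masked to the module, optionally restricted
#' to one direction, and scored against the TF-target map.
#'
#' @param stats Gene statistics tibble.
#' @param module_genes Module gene ids (masking set).
#' @param tf_map A transcription-factor `feature_map`.
#' @param direction `"all"`, `"up"` or `"down"`.
#' @param module_id Label recorded in the output.
#' @inheritParams reporter_scores
#' @return A reporter-score tibble.
#' @export
reporter_tfs_for_module <- function(stats, module_genes, tf_map,
                                    direction = c("all", "up", "down"),
                                    module_id = "module",
                                    n_background = 10000, seed = 1L) {
  direction <- match.arg(direction)
  masked <- module_mask(stats, module_genes)
  if (direction != "all") masked <- directional_subset(masked, direction)
  reporter_scores(gene_zscores(masked), tf_map,
                  n_background = n_background, seed = seed,
                  direction_context = direction, module_context = module_id)
}
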