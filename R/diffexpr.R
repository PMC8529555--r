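#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction, returned in input order. Thin,
#' contract-checked wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Two-group differential expression
#'
#' Per-gene contrast of `group2` over `group1`: fold change on mean TPM with
#' pseudocount 1, significance from a two-sided Wilcoxon rank-sum test on
#' log2(TPM + 1) (exact when both groups have at most 10 samples and no
#' ties, normal approximation with tie correction otherwise), BH adjustment
#' over all tested genes. The negative-binomial machinery of count-based DE
#' tools is intentionally out of scope; externally computed tables can be
#' supplied through [import_de_table()].
#'
#' @param expr An [expr_matrix] on TPM scale.
#' @param metadata Data frame with columns `sample_id` and `group_label`.
#' @param group1 Reference group label (denominator of the fold change).
#' @param group2 Test group label.
#' @param deg_alpha Adjusted-p threshold used for the `direction` call.
#' @return A tibble with columns `gene_id`, `log2fc`, `p_value`, `adj_p`,
#'   `direction` (`up`, `down` or `ns`).
#' @export
compute_de <- function(expr, metadata, group1, group2, deg_alpha = 0.01) {
  stopifnot(is_expr_matrix(expr))
  md <- tibble::as_tibble(metadata)
  for (g in c(group1, group2)) {
    if (!g %in% md$group_label) stop("unknown group label: ", g, call. = FALSE)
  }
  s1 <- intersect(colnames(expr), md$sample_id[md$group_label == group1])
  s2 <- intersect(colnames(expr), md$sample_id[md$group_label == group2])
  if (length(s1) < 2 || length(s2) < 2) {
    stop("each group needs at least 2 samples present in the matrix", call. = FALSE)
  }
  m1 <- unclass(expr)[, s1, drop = FALSE]
  m2 <- unclass(expr)[, s2, drop = FALSE]
  log2fc <- unname(log2((rowMeans(m2) + 1) / (rowMeans(m1) + 1)))
  l1 <- log2(m1 + 1); l2 <- log2(m2 + 1)
  exact_ok <- length(s1) <= 10 && length(s2) <= 10
  p <- vapply(seq_len(nrow(expr)), function(i) {
    x <- l2[i, ]; y <- l1[i, ]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided",
                  exact = exact_ok, correct = !exact_ok)$p.value
    )
  }, numeric(1))
  p[is.na(p)] <- 1
  gene_stat_table(tibble::tibble(
    gene_id = rownames(expr),
    log2fc = log2fc,
    p_value = p,
    adj_p = bh_adjust(p)
  ), deg_alpha = deg_alpha)
}

#' Assign DE direction calls to a gene statistics table
#'
#' `up` means positive fold change with adjusted p below `deg_alpha`,
#' `down` the mirror image, `ns` everything else.
#'
#' @param stats Data frame with `gene_id`, `log2fc`, `p_value`, `adj_p`.
#' @param deg_alpha Adjusted-p threshold.
#' @return The tibble with a recomputed `direction` column.
#' @export
gene_stat_table <- function(stats, deg_alpha = 0.01) {
  stats <- tibble::as_tibble(stats)
  need <- c("gene_id", "log2fc", "p_value", "adj_p")
  if (!all(need %in% names(stats))) {
    stop("gene stats need columns: ", paste(setdiff(need, names(stats)),
                                            collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(stats$gene_id)) stop("duplicate gene ids", call. = FALSE)
  dplyr::mutate(
    stats,
    direction = dplyr::case_when(
      .data$log2fc > 0 & .data$adj_p < deg_alpha ~ "up",
      .data$log2fc < 0 & .data$adj_p < deg_alpha ~ "down",
      TRUE ~ "ns"
    )
  )
}

#' Import an externally computed DE table
#'
#' Accepts the per-gene output of any DE tool as a TSV with columns
#' `gene`/`gene_id`, `log2fc`, `p`/`p_value`, `adj_p`. Rows with missing
#' p-values are dropped (count reported); directions are recomputed at
#' `deg_alpha`.
#'
#' @param path Path to the TSV file.
#' @param deg_alpha Adjusted-p threshold for direction calls.
#' @return A gene statistics tibble as from [compute_de()].
#' @export
import_de_table <- function(path, deg_alpha = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  nm <- names(df)
  ren <- c(gene = "gene_id", p = "p_value", pvalue = "p_value", padj = "adj_p")
  for (old in names(ren)) nm[nm == old] <- ren[[old]]
  names(df) <- nm
  need <- c("gene_id", "log2fc", "p_value", "adj_p")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("DE table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df[, need])
  n_drop <- sum(is.na(df$p_value) | is.na(df$adj_p))
  if (n_drop > 0) {
    message(sprintf("dropped %d row(s) with missing p-values", n_drop))
    df <- df[!(is.na(df$p_value) | is.na(df$adj_p)), ]
  }
  gene_stat_table(df, deg_alpha = deg_alpha)
}

#' Fraction of module genes called DE in a given direction
#'
#' Convenience summary used when asking how strongly a co-expression module
#' is perturbed in a contrast: the percentage of the module's genes whose
#' direction call matches.
#'
#' @param stats Gene statistics tibble with a `direction` column.
#' @param module_genes Character vector of module gene ids.
#' @param direction `"up"` or `"down"`.
#' @return A one-row tibble with `n_module`, `n_called`, `percent`.
#' @export
module_de_fraction <- function(stats, module_genes, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sub <- stats[stats$gene_id %in% module_genes, ]
  n_called <- sum(sub$direction == direction)
  tibble::tibble(
    n_module = length(module_genes),
    n_called = n_called,
    percent = 100 * n_called / length(module_genes)
  )
}
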