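#' Remove lowly expressed genes
#'
#' Genes whose per-gene summary statistic (median by default) falls strictly
#' below the threshold are dropped before network construction; survivor
#' order is preserved and the removal count is reported.
#'
#' @param expr An [expr_matrix] on TPM scale.
#' @param stat `"median"` (default) or `"mean"`.
#' @param threshold Expression floor; default 1 TPM.
#' @return The filtered [expr_matrix].
#' @export
filter_low_expression <- function(expr, stat = c("median", "mean"), threshold = 1) {
  stat <- match.arg(stat)
  stopifnot(is_expr_matrix(expr))
  s <- apply(unclass(expr), 1, if (stat == "median") median else mean)
  keep <- s >= threshold
  if (!any(keep)) stop("no genes pass expression filter", call. = FALSE)
  if (any(!keep)) {
    message(sprintf("removed %d of %d genes with %s TPM < %g",
                    sum(!keep), length(keep), stat, threshold))
  }
  expr[keep, , drop = FALSE]
}

#' All-pairs Spearman correlation
#'
#' One record per unordered gene pair: Spearman's rho with midrank ties and
#' a two-sided p-value (exact permutation null for n <= 9 samples, the usual
#' t approximation otherwise). Computed blockwise as Pearson correlation on
#' rank-transformed rows so memory stays bounded; the output is identical
#' for any block size. A zero-variance gene yields rho = 0, p = 1 for its
#' pairs, with a warning.
#'
#' @param expr An [expr_matrix] with at least 3 samples.
#' @param block_size Number of genes correlated per block.
#' @return A tibble with columns `gene_a`, `gene_b` (lexicographic pair
#'   order), `rho`, `p_value`.
#' @export
spearman_all_pairs <- function(expr, block_size = 2000L) {
  stopifnot(is_expr_matrix(expr))
  n <- ncol(expr); g <- nrow(expr)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (g < 2) stop("need at least 2 genes", call. = FALSE)
  m <- unclass(expr)
  ranks <- t(apply(m, 1, rank))          # midranks
  constant <- apply(m, 1, function(v) all(v == v[1]))
  if (any(constant)) {
    warning(sprintf("%d zero-variance gene(s); their pairs get rho = 0, p = 1",
                    sum(constant)), call. = FALSE)
  }
  rs <- ranks - rowMeans(ranks)
  norms <- sqrt(rowSums(rs^2))
  norms[norms == 0] <- 1               # constant genes: rho forced to 0 below
  rs <- rs / norms
  rs[constant, ] <- 0

  genes <- rownames(expr)
  blocks <- split(seq_len(g), ceiling(seq_len(g) / block_size))
  pieces <- list()
  for (bi in seq_along(blocks)) {
    i_idx <- blocks[[bi]]
    for (bj in bi:length(blocks)) {
      j_idx <- blocks[[bj]]
      cc <- tcrossprod(rs[i_idx, , drop = FALSE], rs[j_idx, , drop = FALSE])
      idx <- which(outer(i_idx, j_idx, `<`), arr.ind = TRUE)
      if (nrow(idx) == 0) next
      pieces[[length(pieces) + 1]] <- tibble::tibble(
        ia = i_idx[idx[, 1]], ja = j_idx[idx[, 2]],
        rho = pmin(1, pmax(-1, cc[idx]))
      )
    }
  }
  out <- dplyr::bind_rows(pieces)
  out <- out[order(out$ia, out$ja), ]

  both_ok <- !(constant[out$ia] | constant[out$ja])
  out$rho[!both_ok] <- 0
  if (n <= 9) {
    p <- rep(1, nrow(out))
    for (k in which(both_ok)) {
      p[k] <- suppressWarnings(
        cor.test(ranks[out$ia[k], ], ranks[out$ja[k], ],
                 method = "spearman", exact = TRUE)$p.value
      )
    }
  } else {
    rho <- out$rho
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    p[abs(rho) >= 1] <- 0
    p[!both_ok] <- 1
  }
  tibble::tibble(
    gene_a = genes[out$ia], gene_b = genes[out$ja],
    rho = out$rho, p_value = pmin(p, 1)
  )
}

#' Build a co-expression network
#'
#' From an expression-filtered matrix: all-pairs Spearman, BH-FDR over every
#' tested pair, retention of positively correlated pairs with FDR below
#' `edge_fdr_alpha`, then of those only the top `top_edge_fraction` ranked
#' by rho descending (ties at the cutoff broken by smaller p, then
#' lexicographic pair id, so the edge set is deterministic).
#'
#' @param expr An [expr_matrix], already expression-filtered.
#' @param config An [analysis_config].
#' @param cohort_id Label stored in the network's provenance.
#' @return A `coexpression_network`: list with `nodes`, `edges` (tibble
#'   `gene_a`, `gene_b`, `rho`, `p_value`, `fdr`) and `provenance`.
#' @export
build_network <- function(expr, config = analysis_config(), cohort_id = "cohort") {
  pairs <- spearman_all_pairs(expr)
  pairs$fdr <- bh_adjust(pairs$p_value)
  sig_pos <- pairs[pairs$rho > 0 & pairs$fdr < config$edge_fdr_alpha, ]
  if (nrow(sig_pos) == 0) stop("no significant positive pairs", call. = FALSE)
  n_keep <- ceiling(config$top_edge_fraction * nrow(sig_pos))
  ord <- order(-sig_pos$rho, sig_pos$p_value, sig_pos$gene_a, sig_pos$gene_b)
  edges <- sig_pos[ord[seq_len(n_keep)], ]
  edges <- edges[order(edges$gene_a, edges$gene_b), ]
  structure(list(
    nodes = rownames(expr),
    edges = tibble::as_tibble(edges),
    provenance = list(
      cohort_id = cohort_id,
      tpm_filter_stat = config$tpm_filter_stat,
      tpm_filter_threshold = config$tpm_filter_threshold,
      edge_fdr_alpha = config$edge_fdr_alpha,
      top_edge_fraction = config$top_edge_fraction,
      top_edge_rule = "top fraction by rho among significant positive pairs",
      n_pairs_tested = nrow(pairs),
      n_significant_positive = nrow(sig_pos)
    )
  ), class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %s: %d nodes, %d edges (of %d pairs tested)\n",
              x$provenance$cohort_id, length(x$nodes), nrow(x$edges),
              x$provenance$n_pairs_tested))
  invisible(x)
}

#' @describeIn build_network Edge list as a tibble.
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @method tidy coexpression_network
#' @export
tidy.coexpression_network <- function(x, ...) x$edges

#' @describeIn build_network One-row summary (node/edge counts, thresholds).
#' @method glance coexpression_network
#' @export
glance.coexpression_network <- function(x, ...) {
  tibble::tibble(
    cohort_id = x$provenance$cohort_id,
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_pairs_tested = x$provenance$n_pairs_tested,
    n_significant_positive = x$provenance$n_significant_positive,
    edge_fdr_alpha = x$provenance$edge_fdr_alpha,
    top_edge_fraction = x$provenance$top_edge_fraction
  )
}

#' Write a network edge list to TSV (with a provenance JSON-ish sidecar)
#' @param network A `coexpression_network`.
#' @param path Output TSV path; provenance goes to `<path>.provenance.yaml`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(network$provenance, paste0(path, ".provenance.yaml"))
  invisible(path)
}

# igraph view of the retained edges; nodes without edges kept as isolates
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
}
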