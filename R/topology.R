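#' Topological statistics of a module
#'
#' Degree and closeness centrality computed on the subgraph induced by the
#' module's genes. Closeness follows the NetworkAnalyzer convention:
#' `(n_c - 1) / sum of distances` within the node's connected component of
#' size `n_c`, so a clique scores exactly 1 and an isolated node scores 0.
#' The node's degree in the full network is also reported for transparency.
#'
#' @param network A `coexpression_network`.
#' @param module_genes Character vector of gene ids, a subset of the
#'   network's nodes.
#' @return A tibble with columns `gene_id`, `degree`, `degree_full`,
#'   `closeness`.
#' @export
module_topology <- function(network, module_genes) {
  module_genes <- unique(module_genes)
  missing <- setdiff(module_genes, network$nodes)
  if (length(missing) > 0) {
    stop("module genes not in network: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  g_full <- as_igraph(network)
  g <- igraph::induced_subgraph(g_full, module_genes)
  deg <- igraph::degree(g)
  deg_full <- igraph::degree(g_full, v = module_genes)
  comp <- igraph::components(g)
  d <- igraph::distances(g)
  clo <- vapply(seq_along(deg), function(i) {
    members <- which(comp$membership == comp$membership[i])
    n_c <- length(members)
    if (n_c == 1) return(0)
    (n_c - 1) / sum(d[i, members])
  }, numeric(1))
  tibble::tibble(
    gene_id = igraph::V(g)$name,
    degree = as.integer(deg),
    degree_full = as.integer(deg_full[igraph::V(g)$name]),
    closeness = clo
  )
}

#' Degree concordance between two modules
#'
#' Spearman correlation of within-module degree over the genes shared by two
#' modules (typically from different cohorts) — high positive concordance
#' indicates a conserved topological structure.
#'
#' @param stats_a,stats_b Topology tibbles from [module_topology()].
#' @return A one-row tibble: `rho`, `p_value`, `n_shared`.
#' @export
degree_concordance <- function(stats_a, stats_b) {
  shared <- dplyr::inner_join(
    stats_a[, c("gene_id", "degree")],
    stats_b[, c("gene_id", "degree")],
    by = "gene_id", suffix = c("_a", "_b")
  )
  if (nrow(shared) < 3) stop("need at least 3 shared genes", call. = FALSE)
  ct <- suppressWarnings(
    cor.test(shared$degree_a, shared$degree_b, method = "spearman")
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_shared = nrow(shared))
}
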