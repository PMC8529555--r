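# Independent oracles used across the suite. Each re-derives the target
# quantity from first principles (enumeration, brute force, closed form) so
# the implementation under test never checks itself.

# Benjamini-Hochberg step-up by the definition: sort ascending,
# q_i = min_{j >= i} p_(j) * n / j, clipped at 1, returned in input order.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  pmin(q_sorted, 1)[order(ord)]
}

# Exhaustive hypergeometric upper tail: universe 1..u with marked set 1..a;
# enumerate every b-subset and count those sharing >= k members with 1..a.
hyper_enum_oracle <- function(u, a, b, k) {
  subsets <- utils::combn(u, b)
  overlaps <- colSums(subsets <= a)
  mean(overlaps >= k)
}

# Product-limit estimator by direct accumulation over sorted distinct times.
km_hand_oracle <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(event == 1 & time == ut[i])
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Build a coexpression_network object directly from an edge data frame,
# for tests that need a graph with known structure.
make_net <- function(edges, nodes = NULL, cohort_id = "test") {
  edges <- tibble::tibble(
    gene_a = pmin(edges[[1]], edges[[2]]),
    gene_b = pmax(edges[[1]], edges[[2]]),
    rho = if (ncol(edges) >= 3) edges[[3]] else 0.9,
    p_value = 1e-6, fdr = 1e-5
  )
  nodes <- nodes %||% sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(
    nodes = nodes, edges = edges,
    provenance = list(cohort_id = cohort_id, tpm_filter_stat = "median",
                      tpm_filter_threshold = 1, edge_fdr_alpha = 0.05,
                      top_edge_fraction = 0.1,
                      n_pairs_tested = length(nodes) * (length(nodes) - 1) / 2,
                      n_significant_positive = nrow(edges))
  ), class = "coexpression_network")
}

# All within-set edges of a clique on the given node labels.
clique_edges <- function(nodes) {
  pairs <- utils::combn(nodes, 2)
  data.frame(a = pairs[1, ], b = pairs[2, ])
}

# Small expression matrix helper.
tiny_expr <- function(values, genes, samples, scale = "tpm") {
  expr_matrix(matrix(values, nrow = length(genes), byrow = TRUE,
                     dimnames = list(genes, samples)), scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One shared small synthetic design for the expensive end-to-end checks,
# generated once per test run.
small_design <- function(seed = 42L) {
  synthetic_design(seed = seed)
}
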