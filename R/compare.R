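#' Jaccard index of two gene sets
#'
#' Size of the intersection over size of the union.
#'
#' @param set_a,set_b Non-empty character vectors (duplicates ignored).
#' @return A single value in \[0, 1\].
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("jaccard_index requires two non-empty sets", call. = FALSE)
  }
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Hypergeometric overlap test between two modules
#'
#' Upper-tail probability of observing at least the realised overlap when
#' `|B|` genes are drawn without replacement from a universe containing
#' `|A|` marked genes: `P(X >= k)` with the observed value included.
#'
#' @param set_a,set_b Gene sets (character vectors).
#' @param universe Either a single integer universe size, or a character
#'   vector of universe genes (both sets must then be contained in it).
#' @param overlap_alpha Significance level for the `significant` flag.
#' @return A one-row tibble: `size_a`, `size_b`, `overlap_count`, `jaccard`,
#'   `universe_size`, `hyper_p`, `significant`.
#' @export
overlap_test <- function(set_a, set_b, universe, overlap_alpha = 0.05) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) == 0 || length(b) == 0) {
    stop("overlap_test requires two non-empty sets", call. = FALSE)
  }
  if (is.character(universe)) {
    u <- unique(universe)
    bad <- c(setdiff(a, u), setdiff(b, u))
    if (length(bad) > 0) {
      stop("set members outside the declared universe: ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
    n_universe <- length(u)
  } else {
    n_universe <- as.integer(universe)
    if (length(a) > n_universe || length(b) > n_universe) {
      stop("set larger than the declared universe", call. = FALSE)
    }
  }
  k <- length(intersect(a, b))
  p <- phyper(k - 1, length(a), n_universe - length(a), length(b),
              lower.tail = FALSE)
  tibble::tibble(
    size_a = length(a), size_b = length(b), overlap_count = k,
    jaccard = k / (length(a) + length(b) - k),
    universe_size = n_universe,
    hyper_p = p,
    significant = p < overlap_alpha
  )
}

#' Score module conservation across cohorts
#'
#' Every cross-cohort module pair is scored with the Jaccard index and the
#' hypergeometric overlap test. The test universe per pair follows
#' `universe_policy`: the intersection of the two cohorts' network node sets
#' (default — the genes eligible to co-occur), their union, or a fixed
#' integer supplied via `universe_size`. Sets are intersected with the pair
#' universe before testing under the intersection policy.
#'
#' @param partitions List of `module_partition` objects (>= 2), each with a
#'   distinct `cohort_id`; their parent networks' node sets must be supplied
#'   unless each partition covers them (node sets are taken as
#'   modules + unassigned).
#' @param universe_policy `"intersection"`, `"union"`, or `"fixed"`.
#' @param universe_size Universe size when `universe_policy = "fixed"`.
#' @param overlap_alpha Significance level.
#' @return A `module_conservation` tibble: one row per cross-cohort module
#'   pair with cohorts, module ids, sizes, overlap, jaccard, hypergeometric
#'   p and significance flag. The policy is recorded as an attribute.
#' @export
all_pairs_conservation <- function(partitions,
                                   universe_policy = c("intersection", "union", "fixed"),
                                   universe_size = NULL,
                                   overlap_alpha = 0.05) {
  universe_policy <- match.arg(universe_policy)
  if (length(partitions) < 2) stop("need at least 2 partitions", call. = FALSE)
  ids <- vapply(partitions, function(p) p$cohort_id, "")
  if (anyDuplicated(ids)) stop("cohort ids must be distinct", call. = FALSE)
  node_sets <- lapply(partitions, function(p) {
    unique(c(unlist(p$modules, use.names = FALSE), p$unassigned))
  })
  rows <- list()
  for (i in seq_along(partitions)) {
    for (j in seq_along(partitions)) {
      if (j <= i) next
      uni <- switch(universe_policy,
        intersection = intersect(node_sets[[i]], node_sets[[j]]),
        union = union(node_sets[[i]], node_sets[[j]]),
        fixed = {
          if (is.null(universe_size)) {
            stop("`universe_size` required for the fixed policy", call. = FALSE)
          }
          as.integer(universe_size)
        }
      )
      if (is.character(uni) && length(uni) == 0) {
        stop(sprintf("cohorts %s and %s share no genes", ids[i], ids[j]),
             call. = FALSE)
      }
      for (ma in names(partitions[[i]]$modules)) {
        for (mb in names(partitions[[j]]$modules)) {
          sa <- partitions[[i]]$modules[[ma]]
          sb <- partitions[[j]]$modules[[mb]]
          if (universe_policy == "intersection") {
            sa <- intersect(sa, uni); sb <- intersect(sb, uni)
          }
          if (length(sa) == 0 || length(sb) == 0) next
          res <- overlap_test(sa, sb, uni, overlap_alpha)
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(cohort_a = ids[i], module_a = ma,
                           cohort_b = ids[j], module_b = mb),
            res
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "universe_policy") <- universe_policy
  attr(out, "overlap_alpha") <- overlap_alpha
  class(out) <- c("module_conservation", class(out))
  out
}

#' Extract consensus modules from a conservation table
#'
#' A consensus module is a maximal clique of modules — at most one per
#' cohort — whose pairwise overlaps are all significant; its consensus gene
#' set is the intersection of the member modules. Cliques are found on the
#' significance graph of module pairs; only cliques spanning
#' `min_cohorts` cohorts are reported.
#'
#' @param conservation A `module_conservation` tibble.
#' @param partitions The same partition list used to build it.
#' @param min_cohorts Minimum number of cohorts a consensus module must
#'   span (default: all cohorts present in the table).
#' @return A tibble with one row per consensus module: `members`
#'   (list-column of "cohort:module" labels), `n_cohorts`, `consensus_genes`
#'   (list-column), `consensus_size`, `min_pairwise_jaccard`.
#' @export
extract_consensus <- function(conservation, partitions, min_cohorts = NULL) {
  ids <- vapply(partitions, function(p) p$cohort_id, "")
  if (is.null(min_cohorts)) {
    min_cohorts <- length(unique(c(conservation$cohort_a, conservation$cohort_b)))
  }
  sig <- conservation[conservation$significant, , drop = FALSE]
  empty <- tibble::tibble(members = list(), n_cohorts = integer(),
                          consensus_genes = list(), consensus_size = integer(),
                          min_pairwise_jaccard = numeric())
  if (nrow(sig) == 0) return(empty)
  va <- paste(sig$cohort_a, sig$module_a, sep = ":")
  vb <- paste(sig$cohort_b, sig$module_b, sep = ":")
  g <- igraph::graph_from_data_frame(data.frame(va, vb), directed = FALSE)
  cliques <- igraph::max_cliques(g, min = min_cohorts)
  if (length(cliques) == 0) return(empty)
  rows <- purrr::map(cliques, function(cl) {
    labels <- sort(names(cl))
    cohorts <- sub(":.*$", "", labels)
    if (anyDuplicated(cohorts) || length(cohorts) < min_cohorts) return(NULL)
    gene_sets <- purrr::map(labels, function(lab) {
      parts <- strsplit(lab, ":", fixed = TRUE)[[1]]
      partitions[[which(ids == parts[1])]]$modules[[parts[2]]]
    })
    consensus <- Reduce(intersect, gene_sets)
    jacc <- utils::combn(length(gene_sets), 2, function(ij) {
      jaccard_index(gene_sets[[ij[1]]], gene_sets[[ij[2]]])
    })
    tibble::tibble(
      members = list(labels),
      n_cohorts = length(labels),
      consensus_genes = list(sort(consensus)),
      consensus_size = length(consensus),
      min_pairwise_jaccard = min(jacc)
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) return(empty)
  out[order(-out$consensus_size), ]
}
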