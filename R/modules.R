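#' Detect co-expression modules
#'
#' Partitions the network into communities by modularity maximisation —
#' Leiden by default (resolution-free modularity objective, unweighted
#' edges), with Louvain available behind the same contract. Communities
#' smaller than `min_module_size` are moved to the unassigned pool; the
#' survivors are relabelled 1..K by decreasing size (ties broken by the
#' lexicographically smallest member gene). The partition is deterministic
#' given `config$rng_seed`.
#'
#' @param network A `coexpression_network` from [build_network()].
#' @param config An [analysis_config]; uses `min_module_size`, `rng_seed`.
#' @param method `"leiden"` (default) or `"louvain"`.
#' @return A `module_partition`: list with `cohort_id`, `modules` (named
#'   list of gene-id vectors, names "1".."K"), `unassigned` (gene ids), and
#'   `modularity` of the full pre-filter partition.
#' @export
detect_modules <- function(network, config = analysis_config(),
                           method = c("leiden", "louvain")) {
  method <- match.arg(method)
  if (length(network$nodes) == 0 || nrow(network$edges) == 0) {
    stop("empty network", call. = FALSE)
  }
  g <- as_igraph(network)
  comm <- with_seed(config$rng_seed, {
    if (method == "leiden") {
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = 1, n_iterations = 10)
    } else {
      igraph::cluster_louvain(g)
    }
  })
  memb <- igraph::membership(comm)
  mod_q <- igraph::modularity(g, memb)
  sets <- split(names(memb), memb)
  keep <- lengths(sets) >= config$min_module_size
  kept <- sets[keep]
  unassigned <- unlist(sets[!keep], use.names = FALSE)
  # size-rank relabelling; deterministic tie-break on smallest member id
  if (length(kept) > 0) {
    first_gene <- vapply(kept, function(s) min(s), "")
    ord <- order(-lengths(kept), first_gene)
    kept <- lapply(kept[ord], sort)
    names(kept) <- as.character(seq_along(kept))
  }
  structure(list(
    cohort_id = network$provenance$cohort_id,
    modules = kept,
    unassigned = sort(unassigned %||% character(0)),
    modularity = mod_q,
    method = method,
    min_module_size = config$min_module_size
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %s: %d module(s) [%s], %d unassigned gene(s)\n",
              x$cohort_id, length(x$modules),
              paste(lengths(x$modules), collapse = ", "),
              length(x$unassigned)))
  invisible(x)
}

#' Long-format module membership table
#'
#' @param partition A `module_partition`.
#' @return A tibble with columns `cohort_id`, `module_id`, `gene_id`
#'   (one row per assigned gene; unassigned genes are not listed).
#' @export
module_gene_table <- function(partition) {
  if (length(partition$modules) == 0) {
    return(tibble::tibble(cohort_id = character(), module_id = integer(),
                          gene_id = character()))
  }
  tibble::tibble(
    cohort_id = partition$cohort_id,
    module_id = rep(as.integer(names(partition$modules)),
                    lengths(partition$modules)),
    gene_id = unlist(partition$modules, use.names = FALSE)
  )
}

#' @describeIn module_gene_table tidy() alias for a partition.
#' @param x A `module_partition`.
#' @param ... Unused.
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) module_gene_table(x)

#' @describeIn module_gene_table One-row summary of a partition.
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(
    cohort_id = x$cohort_id,
    n_modules = length(x$modules),
    n_assigned = sum(lengths(x$modules)),
    n_unassigned = length(x$unassigned),
    largest_module = if (length(x$modules)) max(lengths(x$modules)) else 0L,
    modularity = x$modularity
  )
}

#' Write / read a module partition as TSV
#'
#' The TSV holds the long-format membership table; reading it back restores
#' an equivalent partition (unassigned genes are not round-tripped).
#'
#' @param partition A `module_partition`.
#' @param path TSV path.
#' @return `path` (writer) or a `module_partition` (reader).
#' @export
write_module_table <- function(partition, path) {
  utils::write.table(module_gene_table(partition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_module_table
#' @export
read_module_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = c("character", "integer", "character"))
  mods <- split(df$gene_id, df$module_id)
  mods <- lapply(mods[order(as.integer(names(mods)))], sort)
  structure(list(
    cohort_id = if (nrow(df)) df$cohort_id[1] else "cohort",
    modules = mods,
    unassigned = character(0),
    modularity = NA_real_,
    method = NA_character_,
    min_module_size = NA_integer_
  ), class = "module_partition")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
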