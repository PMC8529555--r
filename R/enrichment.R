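#' Gene-set over-representation analysis
#'
#' Upper-tail hypergeometric test of a query gene list (typically a module)
#' against every set of a collection, with BH correction across the
#' collection. Every set is intersected with the background before testing;
#' sets with no background genes are excluded (count reported).
#'
#' @param query_genes Character vector, a subset of `background_genes`.
#' @param collection Gene-set tibble as from [read_gmt()] (`set_id`,
#'   `description`, list-column `genes`), or a `feature_map` (each feature's
#'   target set is then a gene set).
#' @param background_genes Character vector: the test universe. The
#'   background policy (all network genes, union of detected modules, or a
#'   user list) is the caller's choice and is recorded on the result.
#' @param q_alpha BH q-value threshold for the `enriched` flag.
#' @param background_label Free-text note recorded on the result.
#' @return An `enrichment_result` tibble sorted by p-value: `set_id`,
#'   `description`, `overlap_count`, `query_size`, `set_size`,
#'   `background_size`, `p_value`, `q_value`, `enriched`.
#' @export
enrich <- function(query_genes, collection, background_genes,
                   q_alpha = 0.05, background_label = "user-supplied") {
  query <- unique(query_genes)
  bg <- unique(background_genes)
  if (length(bg) == 0) stop("empty background", call. = FALSE)
  if (length(query) == 0) stop("empty query gene list", call. = FALSE)
  outside <- setdiff(query, bg)
  if (length(outside) > 0) {
    stop("query genes outside the background: ",
         paste(head(outside, 5), collapse = ", "), call. = FALSE)
  }
  if (inherits(collection, "feature_map")) {
    sets <- split(collection$gene, collection$feature_id)
    collection <- tibble::tibble(set_id = names(sets),
                                 description = names(sets),
                                 genes = unname(sets))
  }
  trimmed <- purrr::map(collection$genes, ~ intersect(unique(.x), bg))
  usable <- lengths(trimmed) > 0
  if (any(!usable)) {
    message(sprintf("excluded %d set(s) with no background genes", sum(!usable)))
  }
  if (!any(usable)) {
    stop("no gene set overlaps the background", call. = FALSE)
  }
  sets <- trimmed[usable]
  out <- tibble::tibble(
    set_id = collection$set_id[usable],
    description = collection$description[usable],
    overlap_count = vapply(sets, function(s) length(intersect(query, s)), 0L),
    query_size = length(query),
    set_size = lengths(sets),
    background_size = length(bg)
  )
  out$p_value <- phyper(out$overlap_count - 1, out$set_size,
                        out$background_size - out$set_size,
                        out$query_size, lower.tail = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  out$enriched <- out$q_value < q_alpha
  out <- out[order(out$p_value, out$set_id), ]
  attr(out, "background_label") <- background_label
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Top enriched sets
#' @param result An `enrichment_result`.
#' @param k Number of rows to keep (default 20), taken from the enriched
#'   rows in p-value order.
#' @return The truncated tibble.
#' @export
top_enriched <- function(result, k = 20) {
  utils::head(result[result$enriched, , drop = FALSE], k)
}

#' Transcription-factor enrichment of a module
#'
#' Runs the over-representation machinery with each TF's target set as a
#' gene set: which regulators' targets are over-represented in the module?
#'
#' @param module_genes Character vector of module gene ids.
#' @param tf_map A `feature_map` with `feature_kind = "transcription_factor"`.
#' @param background_genes Test universe (see [enrich()]).
#' @param q_alpha BH q-value threshold.
#' @return An `enrichment_result` tibble, one row per TF with targets in the
#'   background.
#' @export
tf_enrichment <- function(module_genes, tf_map, background_genes, q_alpha = 0.05) {
  if (!inherits(tf_map, "feature_map") ||
      !identical(attr(tf_map, "feature_kind"), "transcription_factor")) {
    stop("`tf_map` must be a transcription_factor feature map", call. = FALSE)
  }
  enrich(module_genes, tf_map, background_genes, q_alpha,
         background_label = "tf-target enrichment")
}
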