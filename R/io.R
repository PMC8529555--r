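#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids (the first header cell is ignored). The body
#' must be entirely numeric and non-negative; missing values are an error,
#' never imputed.
#'
#' @param path Path to the TSV file.
#' @param scale_flag `"tpm"` (default) or `"counts"`.
#' @return An [expr_matrix].
#' @export
read_expression_tsv <- function(path, scale_flag = c("tpm", "counts")) {
  scale_flag <- match.arg(scale_flag)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("expression TSV needs gene ids plus >=1 sample", call. = FALSE)
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id(s) in ", path, ": ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], colnames(df)[-1][bad[2]]), call. = FALSE)
  }
  dimnames(vals) <- list(gene_ids, colnames(df)[-1])
  expr_matrix(vals, scale_flag)
}

#' Write an expression matrix to TSV
#'
#' Full-precision tab-separated output; `read_expression_tsv()` on the result
#' reproduces the input exactly.
#'
#' @param expr An [expr_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(is_expr_matrix(expr))
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @param collection_name Optional label stored on the result.
#' @return A tibble with columns `set_id`, `description` and a list-column
#'   `genes`; attribute `collection_name`.
#' @export
read_gmt <- function(path, collection_name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble::tibble(set_id = character(), description = character(),
                          genes = list())
    attr(out, "collection_name") <- collection_name
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1]), call. = FALSE)
  }
  out <- tibble::tibble(
    set_id = vapply(fields, `[[`, "", 1),
    description = vapply(fields, `[[`, "", 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
  if (any(lengths(out$genes) == 0)) {
    stop("GMT contains an empty gene set", call. = FALSE)
  }
  attr(out, "collection_name") <- collection_name
  out
}

#' Write a gene-set collection to GMT
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set_id, description, genes, ...) {
    paste(c(set_id, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Construct a bipartite feature-to-gene map
#'
#' Features (metabolites, transcription factors, ...) live in a namespace
#' disjoint from genes; every feature must map to at least one gene.
#'
#' @param df Data frame with columns `feature_id` and `gene` (extra columns
#'   such as regulation mode are kept as annotation).
#' @param feature_kind One of `"metabolite"`, `"transcription_factor"`,
#'   `"other"`.
#' @return A tibble of class `feature_map` with one row per (feature, gene)
#'   edge, deduplicated.
#' @export
feature_map <- function(df, feature_kind = c("other", "metabolite",
                                             "transcription_factor")) {
  feature_kind <- match.arg(feature_kind)
  if (!all(c("feature_id", "gene") %in% names(df))) {
    stop("feature map needs `feature_id` and `gene` columns", call. = FALSE)
  }
  out <- tibble::as_tibble(df) |>
    dplyr::distinct(.data$feature_id, .data$gene, .keep_all = TRUE)
  if (nrow(out) == 0) stop("feature map is empty", call. = FALSE)
  attr(out, "feature_kind") <- feature_kind
  class(out) <- c("feature_map", class(out))
  out
}

#' Read TF-target regulatory relationships (TRRUST layout)
#'
#' Four tab-separated columns per line: TF, target gene, regulation mode,
#' reference. Repeated (TF, target) pairs collapse to a single edge.
#'
#' @param path Path to the TSV file.
#' @return A `feature_map` tibble (`feature_id` = TF, `gene` = target,
#'   `mode` kept as annotation) with `feature_kind = "transcription_factor"`.
#' @export
read_tf_targets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no regulatory relationships in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    stop("TF-target file needs at least TF and target columns", call. = FALSE)
  }
  df <- tibble::tibble(
    feature_id = vapply(fields, `[[`, "", 1),
    gene = vapply(fields, `[[`, "", 2),
    mode = vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_, "")
  )
  feature_map(df, "transcription_factor")
}

#' Read a gene-to-metabolite association table
#'
#' Three tab-separated columns with header: gene, metabolite, subsystem —
#' the flat export of a genome-scale metabolic model's gene-metabolite
#' neighbourhoods. The subsystem is carried as a pass-through annotation.
#'
#' @param path Path to the TSV file.
#' @return A `feature_map` tibble (`feature_id` = metabolite) with
#'   `feature_kind = "metabolite"`.
#' @export
read_gene_metabolite_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  need <- c("gene", "metabolite")
  if (!all(need %in% names(df))) {
    stop("gene-metabolite table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(feature_id = df$metabolite, gene = df$gene,
                        subsystem = df[["subsystem"]] %||% NA_character_)
  feature_map(out, "metabolite")
}

#' Read a survival table
#'
#' Three tab-separated columns with header: sample, time (days), event
#' (1 = event observed, 0 = censored). Rows with a survival time of zero
#' days are excluded, with the count reported as a message.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id`, `time`, `event`.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  names(df)[1] <- "sample_id"
  if (ncol(df) < 3) stop("survival table needs sample, time, event columns", call. = FALSE)
  names(df)[2:3] <- c("time", "event")
  survival_table(tibble::as_tibble(df))
}

#' Validate (and zero-day-filter) a survival table
#'
#' @param df Data frame with columns `sample_id`, `time`, `event`.
#' @return The validated tibble; zero-time rows removed with a message.
#' @export
survival_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("sample_id", "time", "event") %in% names(df))) {
    stop("survival table needs `sample_id`, `time`, `event`", call. = FALSE)
  }
  if (any(is.na(df$time)) || any(df$time < 0)) {
    stop("survival times must be non-negative and non-missing", call. = FALSE)
  }
  ev <- df$event
  if (!all(ev %in% c(0, 1))) {
    stop("event must be coded 0 (censored) or 1 (event)", call. = FALSE)
  }
  n_zero <- sum(df$time == 0)
  if (n_zero > 0) {
    message(sprintf("excluded %d sample(s) with zero-day survival time", n_zero))
    df <- df[df$time > 0, , drop = FALSE]
  }
  df$event <- as.integer(df$event)
  df
}

#' Write a survival table to TSV
#' @param df Survival tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature map to TSV
#' @param fm A `feature_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_map <- function(fm, path) {
  utils::write.table(as.data.frame(fm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
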