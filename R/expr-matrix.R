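#' Expression matrix container
#'
#' A genes x samples numeric matrix of non-negative expression values
#' (TPM scale unless flagged as raw counts). Row names are gene ids,
#' column names are sample ids; both must be unique. This is the substrate
#' of every stage of the pipeline.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   dimnames set. All values must be finite and `>= 0`.
#' @param scale_flag Either `"tpm"` or `"counts"`.
#' @return An `expr_matrix`: the validated matrix with a `scale_flag`
#'   attribute.
#' @export
expr_matrix <- function(values, scale_flag = c("tpm", "counts")) {
  scale_flag <- match.arg(scale_flag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix needs gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  structure(values, scale_flag = scale_flag, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale_flag")))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x Object to test or coerce.
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

#' Scale flag of an expression matrix
#' @param x An `expr_matrix`.
#' @return `"tpm"` or `"counts"`.
#' @export
expr_scale <- function(x) attr(x, "scale_flag") %||% "tpm"

# subsetting keeps the class and scale flag
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "scale_flag") <- attr(x, "scale_flag")
    class(out) <- c("expr_matrix", "matrix", "array")
  }
  out
}

#' Tidy an expression matrix into long format
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`.
#' @method tidy expr_matrix
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}
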