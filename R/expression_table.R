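#' Construct an expression table
#'
#' An `ExpressionTable` is the substrate of the classifier: a non-negative
#' numeric matrix with genes in rows and samples (cell states) in columns,
#' carrying a `normalized` flag that records whether the preprocessing chain
#' (per-sample normalization to a fixed total plus pseudocount) has been
#' applied. The classifier only accepts normalized tables, whose values are
#' strictly positive so that fold changes are always defined.
#'
#' @param values numeric matrix (genes x samples) with unique, non-empty
#'   rownames (gene IDs) and colnames (sample IDs). At least two samples are
#'   required.
#' @param normalized logical flag; `TRUE` means the table went through
#'   [normalize_and_pseudocount()] and every value is strictly positive.
#' @return an `ExpressionTable`: the validated matrix with a `normalized`
#'   attribute.
#' @seealso [read_expression_table()], [prepare_matrix()]
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("ES", "CM")))
#' tab <- expression_table(m)
#' is_normalized(tab)
#' @export
expression_table <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must have rownames (gene IDs) and colnames (sample IDs)",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ID(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ID(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (ncol(values) < 2L) {
    stop("an expression table needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s' (NA not permitted)",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  if (isTRUE(normalized) && any(values <= 0)) {
    stop("a normalized table must have strictly positive values", call. = FALSE)
  }
  structure(values, normalized = isTRUE(normalized),
            class = c("ExpressionTable", "matrix", "array"))
}

#' @rdname expression_table
#' @param x object to test / query.
#' @export
is_expression_table <- function(x) inherits(x, "ExpressionTable")

#' @rdname expression_table
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (is_normalized(x)) "normalized" else "raw"))
  cat("samples:", paste(colnames(x), collapse = ", "), "\n")
  n_show <- min(5L, nrow(x))
  print(unclass(x)[seq_len(n_show), , drop = FALSE])
  if (nrow(x) > n_show) cat(sprintf("... and %d more genes\n", nrow(x) - n_show))
  invisible(x)
}

# Subsetting keeps the class and flag when the result is still a gene x sample
# matrix; degenerate selections fall back to base behaviour.
#' @export
`[.ExpressionTable` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && ncol(out) >= 2L) {
    structure(out, normalized = attr(x, "normalized"),
              class = c("ExpressionTable", "matrix", "array"))
  } else {
    out
  }
}
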