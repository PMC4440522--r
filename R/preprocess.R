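#' Preprocessing configuration
#'
#' Parameters of the preprocessing chain applied before classification:
#' per-sample normalization target, pseudocount, and the quality-status token
#' that marks an isoform's FPKM as usable during gene-level aggregation.
#'
#' @param target_total per-sample total the values are scaled to
#'   (default 1e6, i.e. "FPKM in 1 million of sum").
#' @param pseudocount constant added to every value after scaling (default 1).
#'   Added last, it bounds every fold change involving a near-zero value and
#'   makes low-abundance ratios threshold-stable.
#' @param ok_status quality-status token counted as usable (default `"OK"`).
#' @return a `PreprocessConfig` list.
#' @export
preprocess_config <- function(target_total = 1e6, pseudocount = 1,
                              ok_status = "OK") {
  if (!is.numeric(target_total) || length(target_total) != 1L ||
      target_total <= 0) {
    stop("target_total must be a positive number", call. = FALSE)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount < 0) {
    stop("pseudocount must be non-negative", call. = FALSE)
  }
  structure(list(target_total = target_total, pseudocount = pseudocount,
                 ok_status = as.character(ok_status)),
            class = "PreprocessConfig")
}

#' Aggregate isoform FPKM to gene level
#'
#' The FPKM of a gene in a sample is the sum of its isoforms' FPKM over rows
#' whose quality status equals `config$ok_status`. A gene whose isoforms are
#' all non-OK in a sample gets 0 there (it is only removed later if it is 0 in
#' every sample). Gene and sample order follow first appearance in the table.
#'
#' @param iso an [isoform_table()].
#' @param config a [preprocess_config()].
#' @return a raw [expression_table()], one row per distinct gene.
#' @export
aggregate_isoforms <- function(iso, config = preprocess_config()) {
  stopifnot(inherits(iso, "IsoformTable") || is.data.frame(iso))
  if (!nrow(iso)) stop("isoform table is empty", call. = FALSE)
  genes <- unique(iso$gene_id)
  samples <- unique(iso$sample_id)
  g <- factor(iso$gene_id, levels = genes)
  s <- factor(iso$sample_id, levels = samples)
  ok <- iso$status == config$ok_status
  values <- matrix(0, length(genes), length(samples),
                   dimnames = list(genes, samples))
  if (any(ok)) {
    sums <- tapply(iso$fpkm[ok], list(g[ok], s[ok]), sum, default = 0)
    values[rownames(sums), colnames(sums)] <- sums
  }
  expression_table(values, normalized = FALSE)
}

#' Remove genes with all-zero expression
#'
#' Keeps exactly the genes with at least one strictly positive value,
#' preserving order. Operates on raw tables only (filtering after
#' normalization would change nothing but the invariant is kept tight).
#'
#' @param table a raw [expression_table()].
#' @return the filtered table.
#' @export
drop_all_zero_genes <- function(table) {
  stopifnot(is_expression_table(table))
  if (is_normalized(table)) {
    stop("drop_all_zero_genes() expects a raw (unnormalized) table",
         call. = FALSE)
  }
  keep <- rowSums(unclass(table) > 0) > 0L
  if (!any(keep)) {
    stop("no genes left after removing all-zero rows", call. = FALSE)
  }
  table[keep, , drop = FALSE]
}

#' Per-sample normalization and pseudocount
#'
#' Each value `v` in sample `s` becomes
#' `v * target_total / colsum(s) + pseudocount`, so that every sample's total
#' (before the pseudocount) equals `target_total` and every value is at least
#' `pseudocount`. Scaling one sample's raw column by any positive constant
#' leaves its output unchanged.
#'
#' @param table a raw [expression_table()] with strictly positive column sums.
#' @param config a [preprocess_config()].
#' @return a normalized [expression_table()].
#' @export
normalize_and_pseudocount <- function(table, config = preprocess_config()) {
  stopifnot(is_expression_table(table))
  if (is_normalized(table)) {
    stop("table is already normalized", call. = FALSE)
  }
  totals <- colSums(unclass(table))
  if (any(totals <= 0)) {
    stop("zero column sum in sample(s): ",
         paste(colnames(table)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  values <- sweep(unclass(table), 2L, config$target_total / totals, `*`) +
    config$pseudocount
  expression_table(values, normalized = TRUE)
}

#' Run the full preprocessing chain
#'
#' Composition, in fixed order: isoform-to-gene aggregation (when the input is
#' an isoform table), all-zero gene removal, per-sample normalization,
#' pseudocount. The result is classifier-ready.
#'
#' @param x an [isoform_table()] or a raw [expression_table()].
#' @param config a [preprocess_config()].
#' @return a normalized [expression_table()].
#' @export
prepare_matrix <- function(x, config = preprocess_config()) {
  if (inherits(x, "IsoformTable")) {
    x <- aggregate_isoforms(x, config)
  }
  if (!is_expression_table(x)) {
    stop("input must be an IsoformTable or ExpressionTable", call. = FALSE)
  }
  normalize_and_pseudocount(drop_all_zero_genes(x), config)
}
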