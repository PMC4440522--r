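#' Map an external gene list onto the category space
#'
#' Given classification records for the full run and an externally predicted
#' gene list (for instance, candidate regulators ranked by chromatin
#' signature), tabulates how the list's genes distribute over the nominal
#' categories. Percentages are over matched genes only and sum to 100;
#' unmatched IDs are listed, not counted.
#'
#' @param records a `gepa_records` table.
#' @param external a [gene_list()] (or character vector).
#' @param list_name label carried into the result.
#' @param grouping optional named character vector mapping fine categories to
#'   coarser display groups (e.g. collapsing all multi-lineage categories
#'   containing CM); ungrouped categories keep their own label.
#' @return a `CategoryDistribution` list: `list_name`, `counts`, `percentages`
#'   (zero-filled over all nominal categories, or over `grouping` targets),
#'   `n_matched`, `n_unmatched`, `unmatched_ids`.
#' @export
map_external_list <- function(records, external, list_name = "external",
                              grouping = NULL) {
  stopifnot(inherits(records, "gepa_records"))
  ids <- as.character(external)
  matched <- records[records$gene_id %in% ids, ]
  if (!nrow(matched)) {
    stop("no external-list IDs present among the records", call. = FALSE)
  }
  sample_ids <- attr(records, "sample_ids")
  levels_ <- enumerate_categories(sample_ids, include_sentinels = TRUE)
  pat <- matched$pattern
  if (!is.null(grouping)) {
    mapped <- grouping[pat]
    pat <- ifelse(is.na(mapped), pat, mapped)
    levels_ <- unique(c(setdiff(levels_, names(grouping)), unname(grouping)))
  }
  counts <- table(factor(pat, levels = levels_))
  counts <- stats::setNames(as.integer(counts), levels_)
  structure(list(
    list_name = list_name,
    counts = counts,
    percentages = 100 * counts / nrow(matched),
    n_matched = nrow(matched),
    n_unmatched = sum(!(ids %in% records$gene_id)),
    unmatched_ids = setdiff(ids, records$gene_id)
  ), class = "CategoryDistribution")
}

#' @export
print.CategoryDistribution <- function(x, ...) {
  cat(sprintf("category distribution of '%s': %d matched, %d unmatched\n",
              x$list_name, x$n_matched, x$n_unmatched))
  nz <- x$percentages[x$counts > 0]
  print(round(nz[order(-nz)], 2))
  invisible(x)
}

#' Percent-of-sum specificity profile
#'
#' Expresses each gene's value in a sample as the percentage of that gene's
#' summed expression over all samples, the display transform of
#' relative-specificity heatmaps. Every row sums to 100 and the profile is
#' invariant under per-gene scaling.
#'
#' @param table a normalized [expression_table()].
#' @param gene_ids genes to profile (default all); unknown IDs are an error.
#' @return numeric matrix of percentages (genes x samples).
#' @export
percent_of_sum <- function(table, gene_ids = rownames(table)) {
  stopifnot(is_expression_table(table))
  if (!is_normalized(table)) {
    stop("percent_of_sum() expects a normalized table", call. = FALSE)
  }
  unknown <- setdiff(gene_ids, rownames(table))
  if (length(unknown)) {
    stop("unknown gene ID(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- unclass(table)[gene_ids, , drop = FALSE]
  sweep(m, 1L, rowSums(m), `/`) * 100
}

#' Classify splicing isoforms
#'
#' Runs the same chain at isoform granularity: keep usable rows (quality
#' status equal to `config$ok_status`), build the isoform x sample matrix,
#' drop all-zero isoforms, normalize per sample over the isoform totals, add
#' the pseudocount, and classify each isoform. Normalization is over the
#' isoform matrix itself, not inherited from gene-level totals.
#'
#' @param iso an [isoform_table()].
#' @param config a [preprocess_config()].
#' @param threshold fold-change threshold > 1.
#' @return a `gepa_records` table keyed by isoform ID, with an extra
#'   `parent_gene` column for [detect_isoform_switches()].
#' @export
classify_isoforms <- function(iso, config = preprocess_config(),
                              threshold = 2.5) {
  stopifnot(inherits(iso, "IsoformTable"))
  ok <- iso[iso$status == config$ok_status, , drop = FALSE]
  if (!nrow(ok)) stop("no usable (OK) isoform rows", call. = FALSE)
  isoforms <- unique(ok$isoform_id)
  samples <- unique(iso$sample_id)
  f_iso <- factor(ok$isoform_id, levels = isoforms)
  f_s <- factor(ok$sample_id, levels = samples)
  values <- tapply(ok$fpkm, list(f_iso, f_s), sum, default = 0)
  values <- matrix(as.numeric(values), nrow = length(isoforms),
                   dimnames = list(isoforms, samples))
  tab <- prepare_matrix(expression_table(values, normalized = FALSE), config)
  rec <- classify_matrix(tab, threshold)
  parent <- ok$gene_id[match(rec$gene_id, ok$isoform_id)]
  rec$parent_gene <- parent
  rec
}

#' Detect isoform switches
#'
#' A gene switches isoform usage when at least two of its isoforms fall in
#' different categories AND at least one of them is lineage-enriched (two
#' discordant non-enriched sentinels do not count). Genes with fewer than two
#' classified isoforms pass through unflagged. The call is independent of
#' isoform order; the reported discordant pair is the first enriched category
#' against the first category differing from it, in isoform input order.
#'
#' @param iso_records isoform-level records from [classify_isoforms()] (must
#'   carry `parent_gene`).
#' @return data.frame with one row per gene: `gene_id`, `n_isoforms`,
#'   `isoform_ids` (comma-joined), `patterns` (comma-joined, isoform order),
#'   `switch_flag`, `reason` (`"A|B"` discordant pair, or why not flagged).
#' @export
detect_isoform_switches <- function(iso_records) {
  stopifnot(inherits(iso_records, "gepa_records"))
  if (is.null(iso_records$parent_gene)) {
    stop("records lack parent_gene; use classify_isoforms()", call. = FALSE)
  }
  genes <- unique(iso_records$parent_gene)
  rows <- lapply(genes, function(g) {
    sub <- iso_records[iso_records$parent_gene == g, ]
    pats <- sub$pattern
    if (nrow(sub) < 2L) {
      flag <- FALSE; reason <- "single_isoform"
    } else if (length(unique(pats)) < 2L) {
      flag <- FALSE; reason <- "concordant"
    } else if (!any(sub$kind == "enriched")) {
      flag <- FALSE; reason <- "no_enriched_isoform"
    } else {
      flag <- TRUE
      a <- pats[sub$kind == "enriched"][1L]
      b <- pats[pats != a][1L]
      reason <- paste(a, b, sep = "|")
    }
    data.frame(gene_id = g, n_isoforms = nrow(sub),
               isoform_ids = paste(sub$gene_id, collapse = ","),
               patterns = paste(pats, collapse = ","),
               switch_flag = flag, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Restrict records to an annotation subset
#'
#' Convenience for annotation-defined screens such as lineage-enriched
#' lncRNAs: keeps the records whose gene IDs appear in the annotation list and
#' tabulates their category distribution.
#'
#' @param records a `gepa_records` table.
#' @param annotation a [gene_list()] (or character vector) of annotated IDs.
#' @param list_name label for the distribution.
#' @return list with `records` (the restricted `gepa_records`) and
#'   `distribution` (a `CategoryDistribution`).
#' @export
subset_by_annotation <- function(records, annotation,
                                 list_name = "annotation") {
  stopifnot(inherits(records, "gepa_records"))
  ids <- as.character(annotation)
  keep <- records$gene_id %in% ids
  if (!any(keep)) {
    stop("annotation list has no overlap with the records", call. = FALSE)
  }
  sub <- records[keep, , drop = FALSE]
  attr(sub, "sample_ids") <- attr(records, "sample_ids")
  attr(sub, "threshold") <- attr(records, "threshold")
  class(sub) <- c("gepa_records", "data.frame")
  list(records = sub,
       distribution = map_external_list(records, ids, list_name = list_name))
}
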