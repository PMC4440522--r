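#' Classify one gene's expression pattern
#'
#' The pattern rule, applied to one gene measured in `N >= 2` samples with
#' strictly positive (pseudocounted) values:
#'
#' 1. Sort the samples by the gene's expression in descending order (ties keep
#'    the supplied sample order; a tie never changes the category since its
#'    ratio is 1).
#' 2. Scan consecutive sorted pairs from the top. At the first pair whose fold
#'    change (higher / lower) is greater than or equal to the threshold, stop:
#'    the gene is enriched in the samples above the cut.
#' 3. If no consecutive pair reaches the threshold, the gene is `"Even"` when
#'    the overall max/min ratio is below the threshold, otherwise
#'    `"Gradient"`.
#'
#' Comparisons are exact (`>=` the threshold, no epsilon); equality of max/min
#' with the threshold yields `"Gradient"` ("Even" requires the ratio to be
#' strictly smaller).
#'
#' @param values numeric vector of positive expression values, one per sample.
#' @param sample_ids sample names in the user-supplied (canonical) order;
#'   defaults to `names(values)`.
#' @param threshold fold-change threshold, a number > 1 (default 2.5).
#' @param gene_id optional gene identifier carried into the record.
#' @return a one-row classification record (see [classify_matrix()]).
#' @examples
#' classify_gene(c(ES = 1, MCP = 30, CM = 100, SM = 12, EC = 2))
#' @export
classify_gene <- function(values, sample_ids = names(values), threshold = 2.5,
                          gene_id = "gene") {
  check_threshold(threshold)
  if (is.null(sample_ids)) {
    stop("sample_ids required (or pass a named vector)", call. = FALSE)
  }
  if (length(values) != length(sample_ids) || length(values) < 2L) {
    stop("need one value per sample and at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite (apply the pseudocount first)",
         call. = FALSE)
  }
  core <- classify_core(as.numeric(values), threshold)
  new_records(
    gene_id = gene_id,
    pattern = pattern_string(core$cut, core$ord, sample_ids),
    kind = core$kind,
    n_enriched_samples = core$cut,
    decision_fold_change = core$fc,
    sorted_sample_order = paste(sample_ids[core$ord], collapse = ">"),
    sample_ids = sample_ids,
    threshold = threshold
  )
}

# Scan engine shared by classify_gene()/classify_matrix(). Returns the
# descending order (stable in the original index for ties), the cut size
# (0 for Even/Gradient), the kind, and the decision fold change.
classify_core <- function(v, threshold) {
  ord <- order(v, decreasing = TRUE, method = "radix")
  s <- v[ord]
  n <- length(s)
  ratios <- s[-n] / s[-1L]
  hit <- which(ratios >= threshold)
  if (length(hit)) {
    k <- hit[1L]
    list(ord = ord, cut = k, kind = "enriched", fc = ratios[k])
  } else {
    span <- s[1L] / s[n]
    list(ord = ord, cut = 0L,
         kind = if (span < threshold) "even" else "gradient", fc = span)
  }
}

# Canonical category string: enriched samples joined by "&" in the
# user-supplied sample order (not descending-expression order), so that the
# same subset always yields the same key.
pattern_string <- function(cut, ord, sample_ids) {
  if (cut == 0L) return(NA_character_)  # filled by caller for sentinels
  enriched <- sort(ord[seq_len(cut)])
  paste(sample_ids[enriched], collapse = "&")
}

new_records <- function(gene_id, pattern, kind, n_enriched_samples,
                        decision_fold_change, sorted_sample_order,
                        sample_ids, threshold) {
  pattern[kind == "even"] <- "Even"
  pattern[kind == "gradient"] <- "Gradient"
  df <- data.frame(
    gene_id = gene_id, pattern = pattern, kind = kind,
    n_enriched_samples = n_enriched_samples,
    decision_fold_change = decision_fold_change,
    sorted_sample_order = sorted_sample_order,
    stringsAsFactors = FALSE
  )
  attr(df, "sample_ids") <- sample_ids
  attr(df, "threshold") <- threshold
  class(df) <- c("gepa_records", "data.frame")
  df
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 1) {
    stop("threshold must be a single number > 1", call. = FALSE)
  }
  invisible(threshold)
}

#' Classify every gene of a normalized expression table
#'
#' Applies [classify_gene()] independently to each row. The input must have
#' gone through [prepare_matrix()] (or carry `normalized = TRUE`): the
#' pseudocount guarantees positive values so every fold change is defined.
#'
#' @param table a normalized [expression_table()].
#' @param threshold fold-change threshold > 1 (default 2.5).
#' @return a `gepa_records` data.frame, one row per gene in input order, with
#'   columns `gene_id`, `pattern` (canonical `&`-joined category, `"Even"` or
#'   `"Gradient"`), `kind` (`"enriched"`/`"even"`/`"gradient"`),
#'   `n_enriched_samples`, `decision_fold_change`, `sorted_sample_order`.
#'   The run's `sample_ids` and `threshold` travel as attributes.
#' @export
classify_matrix <- function(table, threshold = 2.5) {
  stopifnot(is_expression_table(table))
  if (!is_normalized(table)) {
    stop("classify_matrix() needs a normalized table; run prepare_matrix()",
         call. = FALSE)
  }
  check_threshold(threshold)
  if (!nrow(table)) stop("table has no genes", call. = FALSE)
  sample_ids <- colnames(table)
  m <- unclass(table)
  n_genes <- nrow(m)
  pattern <- character(n_genes)
  kind <- character(n_genes)
  cut <- integer(n_genes)
  fc <- numeric(n_genes)
  ord_str <- character(n_genes)
  for (i in seq_len(n_genes)) {
    core <- classify_core(m[i, ], threshold)
    pattern[i] <- pattern_string(core$cut, core$ord, sample_ids)
    kind[i] <- core$kind
    cut[i] <- core$cut
    fc[i] <- core$fc
    ord_str[i] <- paste(sample_ids[core$ord], collapse = ">")
  }
  new_records(rownames(m), pattern, kind, cut, fc, ord_str,
              sample_ids, threshold)
}

#' Enumerate the nominal category space
#'
#' All proper non-empty sample subsets (sizes 1 to N-1) as canonical category
#' strings, ordered by subset size then by sample order, optionally followed
#' by the sentinels `"Gradient"` and `"Even"`. For N samples that is
#' `2^N - 2` enriched categories (+2 sentinels); with five cell states, 32
#' categories in total.
#'
#' @param sample_ids ordered sample IDs (length >= 2).
#' @param include_sentinels append `"Gradient"` and `"Even"`? Default `TRUE`.
#' @return character vector of category labels.
#' @examples
#' length(enumerate_categories(c("ES", "MCP", "CM", "SM", "EC")))  # 32
#' @export
enumerate_categories <- function(sample_ids, include_sentinels = TRUE) {
  n <- length(sample_ids)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  labels <- unlist(lapply(seq_len(n - 1L), function(k) {
    apply(utils::combn(n, k), 2L, function(idx) {
      paste(sample_ids[idx], collapse = "&")
    })
  }), use.names = FALSE)
  if (include_sentinels) labels <- c(labels, "Gradient", "Even")
  labels
}

#' Tabulate classification records over the nominal category space
#'
#' Zero-filled counts over every nominal category, matching fractions (summing
#' to 1), and aggregate counts for the four headline groups: single-lineage
#' enriched, multi-lineage enriched, Gradient, Even.
#'
#' @param records a `gepa_records` table from [classify_matrix()].
#' @return a `category_counts` list with elements `counts`, `fractions`
#'   (named by category), `aggregates` (named integer vector), `n`.
#' @export
category_counts <- function(records) {
  stopifnot(inherits(records, "gepa_records"), nrow(records) > 0L)
  sample_ids <- attr(records, "sample_ids")
  if (is.null(sample_ids)) {
    stop("records lack the sample_ids attribute", call. = FALSE)
  }
  levels_ <- enumerate_categories(sample_ids, include_sentinels = TRUE)
  unknown <- setdiff(unique(records$pattern), levels_)
  if (length(unknown)) {
    stop("pattern(s) outside the nominal space: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(records$pattern, levels = levels_))
  counts <- stats::setNames(as.integer(counts), levels_)
  aggregates <- c(
    single_lineage = sum(counts[n_samples_in_category(levels_) == 1L]),
    multi_lineage = sum(counts[n_samples_in_category(levels_) > 1L]),
    gradient = counts[["Gradient"]],
    even = counts[["Even"]]
  )
  structure(list(counts = counts, fractions = counts / nrow(records),
                 aggregates = aggregates, n = nrow(records)),
            class = "category_counts")
}

# 0 for the sentinels, otherwise the number of "&"-joined samples.
n_samples_in_category <- function(labels) {
  ifelse(labels %in% c("Gradient", "Even"), 0L,
         lengths(strsplit(labels, "&", fixed = TRUE)))
}

#' @export
print.category_counts <- function(x, ...) {
  cat(sprintf("category counts over %d genes\n", x$n))
  agg <- x$aggregates
  cat(sprintf("  single-lineage %d | multi-lineage %d | Gradient %d | Even %d\n",
              agg[["single_lineage"]], agg[["multi_lineage"]],
              agg[["gradient"]], agg[["even"]]))
  nonzero <- x$counts[x$counts > 0]
  print(nonzero[order(-nonzero)])
  invisible(x)
}
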