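#' False positive rate on negative controls
#'
#' Negative controls (housekeeping genes) should carry no lineage enrichment:
#' any enriched pattern counts as a false positive, while `"Even"` and
#' `"Gradient"` are correct. The denominator is the number of control IDs
#' actually present among the records; absent IDs are reported separately and
#' never deflate the rate.
#'
#' @param records a `gepa_records` table.
#' @param negatives a [gene_list()] (or character vector) of control IDs.
#' @return list with `rate` (exact fraction k/n), `n_false`, `n_matched`,
#'   `n_missing`.
#' @export
false_positive_rate <- function(records, negatives) {
  stopifnot(inherits(records, "gepa_records"))
  hits <- records[records$gene_id %in% as.character(negatives), ]
  if (!nrow(hits)) {
    stop("no negative-control IDs present among the records", call. = FALSE)
  }
  n_false <- sum(hits$kind == "enriched")
  list(rate = n_false / nrow(hits), n_false = n_false,
       n_matched = nrow(hits),
       n_missing = length(negatives) - nrow(hits))
}

#' False negative rate on positive controls
#'
#' A positive control is captured when it receives ANY enriched pattern; the
#' rate is the fraction of matched positives left in `"Even"` or `"Gradient"`.
#' With `strict = TRUE` a control only counts as captured when its enriched
#' samples are exactly the expected ones (`expected` maps gene ID to the
#' canonical category string).
#'
#' @param records a `gepa_records` table.
#' @param positives a [gene_list()] (or character vector) of control IDs.
#' @param strict require the expected lineage, not just any enrichment.
#' @param expected named character vector (gene ID -> category string),
#'   required when `strict = TRUE`.
#' @return list with `rate`, `n_missed`, `n_matched`, `n_missing`.
#' @export
false_negative_rate <- function(records, positives, strict = FALSE,
                                expected = NULL) {
  stopifnot(inherits(records, "gepa_records"))
  hits <- records[records$gene_id %in% as.character(positives), ]
  if (!nrow(hits)) {
    stop("no positive-control IDs present among the records", call. = FALSE)
  }
  captured <- if (strict) {
    if (is.null(expected)) {
      stop("strict = TRUE needs the `expected` gene->category map",
           call. = FALSE)
    }
    hits$kind == "enriched" & hits$pattern == expected[hits$gene_id]
  } else {
    hits$kind == "enriched"
  }
  n_missed <- sum(!captured)
  list(rate = n_missed / nrow(hits), n_missed = n_missed,
       n_matched = nrow(hits),
       n_missing = length(positives) - nrow(hits))
}

#' Sweep classification thresholds against control lists
#'
#' Classifies the table at each threshold and reports the false positive rate
#' on the negatives, the false negative rate on the positives, full category
#' counts, and the recommended threshold: the one minimizing FPR + FNR (ties
#' go to the smallest such threshold).
#'
#' @param table a normalized [expression_table()].
#' @param thresholds strictly increasing fold-change thresholds, each > 1
#'   (default `c(1.5, 2, 2.5, 3)`).
#' @param negatives,positives control [gene_list()]s.
#' @return a `CalibrationReport` list: `thresholds`, `fpr`, `fnr` (exact
#'   fractions, aligned with `thresholds`), `n_negative_found`,
#'   `n_positive_found`, `recommended_threshold`, `category_counts` (one
#'   [category_counts()] per threshold).
#' @export
threshold_sweep <- function(table, thresholds = c(1.5, 2, 2.5, 3),
                            negatives, positives) {
  stopifnot(is_expression_table(table), is_normalized(table))
  if (!length(thresholds)) stop("no thresholds given", call. = FALSE)
  for (t in thresholds) check_threshold(t)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  fpr <- numeric(length(thresholds))
  fnr <- numeric(length(thresholds))
  counts <- vector("list", length(thresholds))
  n_neg <- n_pos <- NA_integer_
  for (i in seq_along(thresholds)) {
    rec <- classify_matrix(table, thresholds[i])
    fp <- false_positive_rate(rec, negatives)
    fn <- false_negative_rate(rec, positives)
    fpr[i] <- fp$rate
    fnr[i] <- fn$rate
    n_neg <- fp$n_matched
    n_pos <- fn$n_matched
    counts[[i]] <- category_counts(rec)
  }
  names(counts) <- format(thresholds)
  structure(list(
    thresholds = thresholds, fpr = fpr, fnr = fnr,
    n_negative_found = n_neg, n_positive_found = n_pos,
    recommended_threshold = thresholds[which.min(fpr + fnr)],
    category_counts = counts
  ), class = "CalibrationReport")
}

#' @export
print.CalibrationReport <- function(x, ...) {
  cat("threshold calibration\n")
  df <- data.frame(threshold = x$thresholds,
                   fpr_pct = round(100 * x$fpr, 1),
                   fnr_pct = round(100 * x$fnr, 1))
  print(df, row.names = FALSE)
  cat(sprintf("negatives matched: %d | positives matched: %d\n",
              x$n_negative_found, x$n_positive_found))
  cat(sprintf("recommended threshold (min FPR+FNR): %g\n",
              x$recommended_threshold))
  invisible(x)
}

#' Serialize a calibration report as JSON
#'
#' Rates are written both as exact fractions and rounded to 0.1% for direct
#' comparison with published figures.
#'
#' @param report a `CalibrationReport` from [threshold_sweep()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(report, path) {
  stopifnot(inherits(report, "CalibrationReport"))
  payload <- list(
    thresholds = report$thresholds,
    fpr = report$fpr,
    fnr = report$fnr,
    fpr_pct_rounded = round(100 * report$fpr, 1),
    fnr_pct_rounded = round(100 * report$fnr, 1),
    n_negative_found = report$n_negative_found,
    n_positive_found = report$n_positive_found,
    recommended_threshold = report$recommended_threshold,
    category_counts = lapply(report$category_counts,
                             function(cc) as.list(cc$counts))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Shuffle an expression matrix (null control)
#'
#' Structured lineage enrichment should vanish under value shuffling.
#' `mode = "global"` (default) permutes all values uniformly across the whole
#' matrix, destroying both gene-level and sample-level structure.
#' `mode = "within_gene"` permutes each gene's values across samples only;
#' this conserves every gene's value multiset, hence its sorted fold-change
#' profile, so a gene's enriched-vs-not status is invariant — only the
#' identity of the enriched samples moves. The contrast between the two modes
#' is itself a useful control. The value multiset and matrix shape are
#' conserved exactly, and the result is deterministic for a fixed seed.
#'
#' @param table an [expression_table()].
#' @param seed integer seed.
#' @param mode `"global"` or `"within_gene"`.
#' @return a shuffled [expression_table()] with the same `normalized` flag.
#' @export
shuffle_matrix <- function(table, seed, mode = c("global", "within_gene")) {
  stopifnot(is_expression_table(table))
  mode <- match.arg(mode)
  m <- unclass(table)
  with_local_seed(seed, {
    if (mode == "global") {
      shuffled <- matrix(sample(as.vector(m)), nrow(m), ncol(m),
                         dimnames = dimnames(m))
    } else {
      shuffled <- t(apply(m, 1L, sample))
      dimnames(shuffled) <- dimnames(m)
    }
  })
  expression_table(shuffled, normalized = is_normalized(table))
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  force(code)
}
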