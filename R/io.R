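#' Read a gene x sample expression matrix
#'
#' Reads a tab-separated table with a mandatory header row: first column gene
#' IDs, remaining columns one sample each. Values must be non-negative numbers
#' with a decimal point; missing values are a hard error (the FPKM pipeline
#' produces none after filtering).
#'
#' @param path path to a TSV file.
#' @param sample_order optional character vector giving the desired column
#'   order. Must be a permutation of the samples present in the file; unknown
#'   or missing names are an error.
#' @return a raw (`normalized = FALSE`) [expression_table()].
#' @export
read_expression_table <- function(path, sample_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 3L) {
    stop("expected a gene-ID column plus at least 2 sample columns in ", path,
         call. = FALSE)
  }
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ID(s) in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  sample_ids <- colnames(df)[-1L]
  values <- matrix(NA_real_, nrow(df), length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | col == "" | toupper(col) == "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                   gene_ids[bad[1L]], sample_ids[j], col[bad[1L]]),
           call. = FALSE)
    }
    neg <- which(num < 0)
    if (length(neg)) {
      stop(sprintf("negative value at gene '%s', sample '%s'",
                   gene_ids[neg[1L]], sample_ids[j]), call. = FALSE)
    }
    values[, j] <- num
  }
  if (!is.null(sample_order)) {
    missing_ <- setdiff(sample_order, sample_ids)
    if (length(missing_)) {
      stop("sample_order names not present in file: ",
           paste(missing_, collapse = ", "), call. = FALSE)
    }
    left_out <- setdiff(sample_ids, sample_order)
    if (length(left_out)) {
      stop("sample_order omits file samples: ",
           paste(left_out, collapse = ", "), call. = FALSE)
    }
    values <- values[, sample_order, drop = FALSE]
  }
  expression_table(values, normalized = FALSE)
}

#' Write an expression matrix as TSV
#'
#' Companion writer to [read_expression_table()]; full-precision values
#' (`%.17g`) so a write-then-read round trip reproduces the matrix exactly.
#'
#' @param table an [expression_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(is_expression_table(table))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(table)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], sprintf("%.17g", table[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a Cufflinks-style isoform tracking table
#'
#' Accepts the `*.fpkm_tracking` dialect: tab-separated with at least the
#' columns `tracking_id`, `gene_id`, `FPKM`, `FPKM_status`. Two layouts are
#' supported: one file per sample (pass `sample_id` to label the rows) or a
#' long-format file with its own sample column (`sample` or `sample_id`).
#' No filtering happens at read time; quality statuses are kept verbatim and
#' only [aggregate_isoforms()] interprets them.
#'
#' @param path path to a tracking file.
#' @param sample_id sample label for a per-sample file; leave `NULL` for a
#'   long-format file carrying its own sample column.
#' @return an isoform table: data.frame with columns `isoform_id`, `gene_id`,
#'   `sample_id`, `fpkm`, `status`.
#' @export
read_isoform_tracking <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("tracking_id", "gene_id", "FPKM", "FPKM_status")
  miss <- setdiff(required, colnames(df))
  if (length(miss)) {
    stop("tracking file missing required column(s) ",
         paste(miss, collapse = ", "), "; present columns: ",
         paste(colnames(df), collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_col <- intersect(c("sample_id", "sample"), colnames(df))[1]
    if (is.na(sample_col)) {
      stop("long-format tracking file needs a 'sample' or 'sample_id' column",
           " (or pass sample_id= for a per-sample file)", call. = FALSE)
    }
    samples <- as.character(df[[sample_col]])
  } else {
    samples <- rep(as.character(sample_id), nrow(df))
  }
  fpkm <- suppressWarnings(as.numeric(df$FPKM))
  if (anyNA(fpkm)) {
    stop("non-numeric FPKM at row ", which(is.na(fpkm))[1L], call. = FALSE)
  }
  if (any(fpkm < 0)) {
    stop("negative FPKM at row ", which(fpkm < 0)[1L], call. = FALSE)
  }
  isoform_table(
    isoform_id = as.character(df$tracking_id),
    gene_id = as.character(df$gene_id),
    sample_id = samples,
    fpkm = fpkm,
    status = as.character(df$FPKM_status)
  )
}

#' Assemble an isoform table
#'
#' @param isoform_id,gene_id,sample_id character vectors, one entry per row.
#' @param fpkm non-negative numeric vector.
#' @param status quality-status tokens (the token `"OK"` marks usable FPKM
#'   downstream; others are kept but excluded from gene aggregation).
#' @return data.frame of class `IsoformTable`.
#' @export
isoform_table <- function(isoform_id, gene_id, sample_id, fpkm, status) {
  if (any(fpkm < 0)) stop("fpkm must be non-negative", call. = FALSE)
  out <- data.frame(
    isoform_id = as.character(isoform_id),
    gene_id = as.character(gene_id),
    sample_id = as.character(sample_id),
    fpkm = as.numeric(fpkm),
    status = as.character(status),
    stringsAsFactors = FALSE
  )
  class(out) <- c("IsoformTable", "data.frame")
  out
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments ignored; duplicates
#' dropped keeping first occurrence.
#'
#' @param path path to the list.
#' @param role one of `"negative_control"`, `"positive_control"`,
#'   `"external"`, `"annotation"`.
#' @return character vector of IDs with a `role` attribute (class `GeneList`).
#' @export
read_gene_list <- function(path,
                           role = c("external", "negative_control",
                                    "positive_control", "annotation")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  ids <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- ids[!duplicated(ids)]
  if (!length(ids)) {
    stop("gene list is empty after removing blanks/comments: ", path,
         call. = FALSE)
  }
  gene_list(ids, role)
}

#' @rdname read_gene_list
#' @param ids character vector of identifiers.
#' @export
gene_list <- function(ids, role = c("external", "negative_control",
                                    "positive_control", "annotation")) {
  role <- match.arg(role)
  ids <- as.character(ids)
  ids <- ids[!duplicated(ids)]
  if (!length(ids)) stop("gene list is empty", call. = FALSE)
  structure(ids, role = role, class = c("GeneList", "character"))
}

#' Write / read classification records as TSV
#'
#' The pattern table has one row per gene with columns `gene_id`, `pattern`
#' (canonical category string, e.g. `"MCP&CM"`, `"Even"`, `"Gradient"`),
#' `n_enriched_samples` (0 for Even/Gradient), `decision_fold_change` (the
#' consecutive ratio that terminated the scan; max/min for Even/Gradient) and
#' `sorted_sample_order` (descending-expression order, `>`-joined). Output is
#' bit-stable for fixed input, and a write-then-read round trip reproduces the
#' records.
#'
#' @param records a classification record table from [classify_matrix()].
#' @param path file path.
#' @return `path` (writer, invisibly) / the records (reader).
#' @export
write_pattern_table <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  out <- data.frame(
    gene_id = records$gene_id,
    pattern = records$pattern,
    n_enriched_samples = records$n_enriched_samples,
    decision_fold_change = sprintf("%.17g", records$decision_fold_change),
    sorted_sample_order = records$sorted_sample_order,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(as.list(out), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_pattern_table
#' @param sample_ids the ordered sample IDs of the run, reattached to the
#'   re-read records (the TSV itself stores only per-gene fields).
#' @export
read_pattern_table <- function(path, sample_ids = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "pattern", "n_enriched_samples",
            "decision_fold_change", "sorted_sample_order")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("pattern table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$decision_fold_change <- as.numeric(df$decision_fold_change)
  df$kind <- ifelse(df$pattern == "Even", "even",
                    ifelse(df$pattern == "Gradient", "gradient", "enriched"))
  df <- df[c("gene_id", "pattern", "kind", "n_enriched_samples",
             "decision_fold_change", "sorted_sample_order")]
  if (!is.null(sample_ids)) attr(df, "sample_ids") <- sample_ids
  class(df) <- c("gepa_records", "data.frame")
  df
}
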