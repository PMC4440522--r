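#' Re-run the published five-state analysis from its distributed files
#'
#' Given the originally distributed expression profiles (gene x sample TSV of
#' raw FPKM for ES, MCP, CM, SM, EC) and the published control lists, runs the
#' full chain at the published threshold and collects the headline quantities:
#' number of classified genes, Even/Gradient percentages, single- and
#' multi-lineage totals, and the control error rates. Nothing here is bundled
#' with the package — the files must be supplied by the user.
#'
#' @param expression_path gene x sample TSV of raw FPKM.
#' @param negatives_path plain-text housekeeping (negative-control) list.
#' @param positives_path plain-text positive-control list.
#' @param threshold fold-change threshold (default 2.5, the published
#'   operating point).
#' @param sample_order optional explicit sample order for the TSV.
#' @return list with `n_classified`, `even_pct`, `gradient_pct`,
#'   `single_lineage_genes`, `multi_lineage_genes`, `fpr_pct`, `fnr_pct`,
#'   `n_negative_found`, `n_positive_found`, and the full `records`.
#' @export
reproduce_published_run <- function(expression_path, negatives_path,
                                    positives_path, threshold = 2.5,
                                    sample_order = NULL) {
  raw <- read_expression_table(expression_path, sample_order = sample_order)
  tab <- prepare_matrix(raw)
  records <- classify_matrix(tab, threshold)
  cc <- category_counts(records)
  fp <- false_positive_rate(records,
                            read_gene_list(negatives_path,
                                           "negative_control"))
  fn <- false_negative_rate(records,
                            read_gene_list(positives_path,
                                           "positive_control"))
  list(
    n_classified = cc$n,
    even_pct = 100 * cc$aggregates[["even"]] / cc$n,
    gradient_pct = 100 * cc$aggregates[["gradient"]] / cc$n,
    single_lineage_genes = cc$aggregates[["single_lineage"]],
    multi_lineage_genes = cc$aggregates[["multi_lineage"]],
    fpr_pct = 100 * fp$rate,
    fnr_pct = 100 * fn$rate,
    n_negative_found = fp$n_matched,
    n_positive_found = fn$n_matched,
    records = records
  )
}
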