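app_records <- function() {
  m <- rbind(
    a1 = c(1, 100, 1, 1, 1), a2 = c(1, 95, 1, 1, 1),
    a3 = c(2, 90, 1, 1, 1), a4 = c(1, 80, 2, 1, 1), a5 = c(1, 85, 1, 1, 2),
    b1 = c(5, 5, 5, 5, 5), b2 = c(7, 7, 8, 8, 7), b3 = c(3, 4, 3, 3, 3),
    c1 = c(100, 60, 40, 25, 16), c2 = c(81, 54, 36, 24, 16)
  )
  colnames(m) <- five_states
  classify_matrix(normalized_table(m), 2.5)
}

test_that("external lists map to zero-filled category distributions", {
  rec <- app_records()
  # 10-gene list: 5 in {MCP}, 3 Even, 2 unmatched -> 62.5% / 37.5% of 8
  dist <- map_external_list(rec, c("a1", "a2", "a3", "a4", "a5",
                                   "b1", "b2", "b3", "zz1", "zz2"))
  expect_equal(dist$n_matched, 8L)
  expect_equal(dist$n_unmatched, 2L)
  expect_setequal(dist$unmatched_ids, c("zz1", "zz2"))
  expect_equal(dist$percentages[["MCP"]], 62.5)
  expect_equal(dist$percentages[["Even"]], 37.5)
  expect_equal(sum(dist$percentages), 100, tolerance = 1e-9)
  expect_length(dist$counts, 32L)

  # the full universe reproduces category_counts
  full <- map_external_list(rec, rec$gene_id)
  cc <- category_counts(rec)
  expect_equal(full$counts, cc$counts)
  expect_equal(full$percentages / 100, cc$fractions, tolerance = 1e-12)

  expect_error(map_external_list(rec, c("nope")), "no external-list")
})

test_that("a user grouping map coarsens the distribution", {
  rec <- app_records()
  grouping <- c(MCP = "progenitor", Gradient = "non-specific",
                Even = "non-specific")
  dist <- map_external_list(rec, rec$gene_id, grouping = grouping)
  expect_equal(dist$counts[["progenitor"]], 5L)
  expect_equal(dist$counts[["non-specific"]], 5L)
  expect_equal(sum(dist$percentages), 100, tolerance = 1e-9)
})

test_that("percent-of-sum rows sum to 100 and reflect relative expression", {
  m <- rbind(flat = rep(4, 5), spike = c(80, 10, 5, 3, 2))
  colnames(m) <- five_states
  tab <- normalized_table(m)
  p <- percent_of_sum(tab)
  expect_equal(unname(p["flat", ]), rep(20, 5))
  expect_equal(unname(p["spike", ]), c(80, 10, 5, 3, 2))
  expect_equal(unname(rowSums(p)), c(100, 100), tolerance = 1e-9)
  # invariant under per-gene scaling
  m2 <- m
  m2["spike", ] <- m2["spike", ] * 7.3
  expect_equal(percent_of_sum(normalized_table(m2)), p)
  expect_error(percent_of_sum(tab, c("flat", "missing")), "missing")
  set.seed(8)
  rand <- normalized_table(random_positive_matrix(50, 5, seed = 8))
  expect_equal(unname(rowSums(percent_of_sum(rand))), rep(100, 50),
               tolerance = 1e-9)
})

test_that("isoform-level classification runs the full chain per isoform", {
  sim <- generate_isoform_table(
    plan = list(FGFR1like = c("ES&MCP", "CM&SM&EC"),
                steady = c("Even", "Even"),
                lone = "EC"),
    sample_ids = five_states, seed = 21)
  rec <- classify_isoforms(sim$iso, threshold = 2.5)
  got <- merge(sim$truth, rec, by.x = "isoform_id", by.y = "gene_id")
  expect_equal(nrow(got), nrow(sim$truth))
  expect_identical(got$pattern.y, got$pattern.x)
  expect_identical(got$gene_id, got$parent_gene)
})

test_that("non-OK isoform rows are excluded from isoform classification", {
  sim <- generate_isoform_table(plan = list(g1 = c("Even", "CM")),
                                sample_ids = five_states, seed = 3,
                                add_non_ok = TRUE)
  rec <- classify_isoforms(sim$iso)
  expect_false(any(grepl("isoX", rec$gene_id)))   # LOWDATA decoy dropped
  expect_error(classify_isoforms(
    isoform_table("i1", "g1", "A", 5, "LOWDATA")), "no usable")
})

test_that("a single dominant isoform reproduces the gene-level pattern", {
  sim <- generate_isoform_table(plan = list(solo = "MCP&CM"),
                                sample_ids = five_states, seed = 12)
  iso_rec <- classify_isoforms(sim$iso)
  gene_tab <- prepare_matrix(aggregate_isoforms(sim$iso))
  gene_rec <- classify_matrix(gene_tab, 2.5)
  expect_identical(
    iso_rec$pattern[iso_rec$parent_gene == "solo"],
    gene_rec$pattern[gene_rec$gene_id == "solo"])
})

test_that("isoform switches need discordant labels with an enriched member", {
  sim <- generate_isoform_table(
    plan = list(switcher = c("ES&MCP", "CM&SM&EC"),
                concordant = c("CM", "CM"),
                sentinels = c("Even", "Gradient"),
                single = "SM"),
    sample_ids = five_states, seed = 4)
  rec <- classify_isoforms(sim$iso)
  calls <- detect_isoform_switches(rec)
  calls <- calls[order(calls$gene_id), ]
  flag <- stats::setNames(calls$switch_flag, calls$gene_id)
  expect_true(flag[["switcher"]])
  expect_false(flag[["concordant"]])
  expect_false(flag[["sentinels"]])   # Gradient vs Even: nothing enriched
  expect_false(flag[["single"]])
  expect_equal(calls$reason[calls$gene_id == "switcher"], "ES&MCP|CM&SM&EC")
  expect_equal(calls$reason[calls$gene_id == "sentinels"],
               "no_enriched_isoform")

  # symmetric in isoform order
  rev_rec <- rec[rev(seq_len(nrow(rec))), ]
  attr(rev_rec, "sample_ids") <- attr(rec, "sample_ids")
  class(rev_rec) <- class(rec)
  calls2 <- detect_isoform_switches(rev_rec)
  expect_equal(stats::setNames(calls2$switch_flag, calls2$gene_id)[names(flag)],
               flag)
})

test_that("annotation subsetting restricts records and tabulates them", {
  rec <- app_records()
  out <- subset_by_annotation(rec, c("a1", "b1"), list_name = "lncRNA")
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$distribution$percentages[["MCP"]], 50)
  expect_equal(out$distribution$percentages[["Even"]], 50)
  # annotation covering everything is the identity
  all_out <- subset_by_annotation(rec, rec$gene_id)
  expect_equal(nrow(all_out$records), nrow(rec))
  expect_error(subset_by_annotation(rec, c("x", "y")), "no overlap")
  # restricted records still work downstream
  cc <- category_counts(out$records)
  expect_equal(sum(cc$counts), 2L)
})
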