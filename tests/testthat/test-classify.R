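test_that("hand-traced five-state examples classify as expected", {
  # highest in CM, then MCP, SM, EC, ES; 100/30 >= 2.5 at the first pair
  r <- classify_gene(c(ES = 1, MCP = 30, CM = 100, SM = 12, EC = 2), threshold = 2.5)
  expect_identical(r$pattern, "CM")
  expect_identical(r$kind, "enriched")
  expect_equal(r$decision_fold_change, 100 / 30)
  expect_identical(r$sorted_sample_order, "CM>MCP>SM>EC>ES")

  # 100/60 < 2.5 but 60/12 >= 2.5: enriched in the top two
  r2 <- classify_gene(c(ES = 1, MCP = 60, CM = 100, SM = 12, EC = 2), threshold = 2.5)
  expect_identical(r2$pattern, "MCP&CM")
  expect_equal(r2$decision_fold_change, 5)
  expect_identical(r2$n_enriched_samples, 2L)

  # all consecutive ratios < 2.5 but max/min = 6.25 >= 2.5
  r3 <- classify_gene(stats::setNames(c(100, 60, 40, 25, 16), five_states),
                      threshold = 2.5)
  expect_identical(r3$pattern, "Gradient")
  expect_equal(r3$decision_fold_change, 100 / 16)

  # flat gene
  expect_identical(classify_gene(stats::setNames(rep(7, 5), five_states))$pattern,
                   "Even")

  # two samples, single comparison
  r5 <- classify_gene(c(hi = 10, lo = 1), threshold = 2.5)
  expect_identical(r5$pattern, "hi")
})

test_that("invalid classifier inputs are rejected", {
  expect_error(classify_gene(c(a = 1, b = 0)), "positive")
  expect_error(classify_gene(c(a = 1)), "at least 2")
  expect_error(classify_gene(c(a = 1, b = 2), threshold = 1), "> 1")
  expect_error(classify_gene(c(a = 1, b = 2), threshold = 0.5), "> 1")
  raw <- expression_table(matrix(1, 2, 2,
                                 dimnames = list(c("a", "b"), c("A", "B"))))
  expect_error(classify_matrix(raw, 2.5), "normalized")
})

test_that("threshold comparisons are exact at the boundaries", {
  # consecutive ratio exactly at the threshold triggers the cut (>=)
  r <- classify_gene(c(A = 25, B = 10, C = 10), threshold = 2.5)
  expect_identical(r$pattern, "A")
  # max/min exactly at the threshold: Gradient, not Even
  r2 <- classify_gene(c(A = 25, B = 15, C = 10), threshold = 2.5)
  expect_identical(r2$pattern, "Gradient")
  expect_equal(r2$decision_fold_change, 2.5)
  # just under on both counts: Even
  r3 <- classify_gene(c(A = 24.9, B = 15, C = 10), threshold = 2.5)
  expect_identical(r3$pattern, "Even")
})

test_that("ties keep the user-supplied sample order in the descending sort", {
  r <- classify_gene(c(Z = 5, A = 5, M = 5, B = 50), threshold = 2.5)
  expect_identical(r$sorted_sample_order, "B>Z>A>M")
  expect_identical(r$pattern, "B")
})

test_that("classify_matrix is per-gene independent and order-preserving", {
  m <- matrix(c(1, 30, 100, 12, 2,
                10, 10, 10, 10, 10,
                100, 60, 40, 25, 16), 3, 5, byrow = TRUE,
              dimnames = list(c("gCM", "gFlat", "gDecay"), five_states))
  rec <- classify_matrix(normalized_table(m), 2.5)
  expect_identical(rec$gene_id, rownames(m))
  expect_identical(rec$pattern, c("CM", "Even", "Gradient"))

  perm <- m[c(3, 1, 2), ]
  rec_perm <- classify_matrix(normalized_table(perm), 2.5)
  expect_identical(rec_perm[order(rec_perm$gene_id), "pattern"],
                   rec[order(rec$gene_id), "pattern"])
})

test_that("classification is equivariant under sample permutation and gene scaling", {
  set.seed(31)
  for (rep in 1:25) {
    v <- stats::setNames(exp(rnorm(5, 2, 1.2)) + 0.5, five_states)
    r <- classify_gene(v, threshold = 2)
    # permute samples: same kind, identically permuted enriched set
    perm <- sample(5)
    rp <- classify_gene(v[perm], sample_ids = five_states[perm], threshold = 2)
    expect_identical(rp$kind, r$kind)
    if (r$kind == "enriched") {
      expect_setequal(strsplit(rp$pattern, "&", fixed = TRUE)[[1]],
                      strsplit(r$pattern, "&", fixed = TRUE)[[1]])
    } else {
      expect_identical(rp$pattern, r$pattern)
    }
    # scale the whole gene: identical record
    rs <- classify_gene(v * exp(runif(1, -3, 3)), threshold = 2)
    expect_identical(rs$pattern, r$pattern)
    expect_equal(rs$decision_fold_change, r$decision_fold_change)
  }
})

test_that("with two samples the Gradient category is unreachable", {
  set.seed(7)
  for (rep in 1:200) {
    r <- classify_gene(c(A = exp(rnorm(1, 1, 2)) + 0.1,
                         B = exp(rnorm(1, 1, 2)) + 0.1),
                       threshold = runif(1, 1.1, 4))
    expect_true(r$kind %in% c("enriched", "even"))
  }
})

test_that("category enumeration covers all proper subsets plus sentinels", {
  c5 <- enumerate_categories(five_states)
  expect_length(c5, 32L)
  expect_identical(c5[1:5], five_states)            # singletons in sample order
  expect_identical(utils::tail(c5, 2), c("Gradient", "Even"))
  expect_false(anyDuplicated(c5) > 0)

  expect_length(enumerate_categories(c("A", "B", "C")), 8L)
  expect_identical(enumerate_categories(c("A", "B"), include_sentinels = FALSE),
                   c("A", "B"))
  expect_error(enumerate_categories("A"), "at least 2")
  expect_error(enumerate_categories(c("A", "A")), "duplicate")
})

test_that("category counts are zero-filled, conserved, and aggregated", {
  m <- matrix(c(100, 1, 1, 1, 1,
                90, 1, 1, 1, 1,
                5, 5, 5, 5, 5,
                100, 60, 40, 25, 16), 4, 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), five_states))
  rec <- classify_matrix(normalized_table(m), 2.5)
  cc <- category_counts(rec)
  expect_equal(cc$counts[["ES"]], 2L)
  expect_equal(cc$counts[["Even"]], 1L)
  expect_equal(cc$counts[["Gradient"]], 1L)
  expect_equal(sum(cc$counts), 4L)                  # partition: every gene once
  expect_length(cc$counts, 32L)
  expect_equal(sum(cc$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(cc$aggregates),
               c(2L, 0L, 1L, 1L))
})
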