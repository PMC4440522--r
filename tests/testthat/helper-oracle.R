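# Independent brute-force pattern rule, kept deliberately separate from the
# package's scan: sort a copy of the values, compute ALL consecutive ratios,
# take the first one at or above the threshold, and derive the enriched set
# by thresholding on the cut VALUE (not by index bookkeeping). Sentinels from
# the overall max/min ratio.
oracle_classify <- function(values, sample_ids, threshold) {
  s <- sort(values, decreasing = TRUE)
  n <- length(s)
  ratios <- s[-n] / s[-1L]
  k <- which(ratios >= threshold)[1L]
  if (!is.na(k)) {
    enriched <- sample_ids[values >= s[k]]
    list(kind = "enriched",
         pattern = paste(sample_ids[sample_ids %in% enriched],
                         collapse = "&"))
  } else if (max(values) / min(values) < threshold) {
    list(kind = "even", pattern = "Even")
  } else {
    list(kind = "gradient", pattern = "Gradient")
  }
}

# Random positive expression-like vectors: log-normal mixture with occasional
# near-ties, spanning several orders of magnitude.
random_positive_matrix <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n_genes * n_samples, mean = 3, sd = 1.5)) + 1,
              n_genes, n_samples)
  ties <- sample.int(n_genes, max(1L, n_genes %/% 20L))
  m[ties, 1:2] <- m[ties, 1L]  # exact ties to exercise stable tie-breaking
  dimnames(m) <- list(sprintf("g%05d", seq_len(n_genes)),
                      paste0("S", seq_len(n_samples)))
  m
}

five_states <- c("ES", "MCP", "CM", "SM", "EC")

# A small classifier-ready table built directly on the normalized scale.
normalized_table <- function(values) {
  expression_table(values, normalized = TRUE)
}
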