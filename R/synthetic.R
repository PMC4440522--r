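#' Specification of a planted gene block
#'
#' Describes `n_genes` genes planted with a known category so that, after the
#' full preprocessing chain and classification at the design threshold, each
#' is recovered exactly when `noise_cv = 0`. Values are designed on the
#' post-normalization scale (so `margin` is the fold change the classifier
#' actually sees at the decision cut) and then mapped back to raw scale.
#'
#' @param pattern a canonical category string (`"CM"`, `"MCP&CM"`, ...,
#'   `"Even"`, `"Gradient"`).
#' @param n_genes number of genes to plant.
#' @param margin for enriched plants, the fold change at the decision cut; for
#'   Gradient plants, the overall max/min ratio. Must be >= the design
#'   threshold. Ignored for Even plants.
#' @param spread maximum ratio inside the enriched and non-enriched blocks
#'   (and the whole spread of an Even gene); must be >= 1 and below the design
#'   threshold.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   noise (0 = exact plants).
#' @param level baseline expression on the normalized scale (low block value).
#' @return a `PlantSpec` list.
#' @export
plant_spec <- function(pattern, n_genes = 1L, margin = 4, spread = 1.2,
                       noise_cv = 0, level = 100) {
  stopifnot(n_genes >= 1L, margin > 1 || pattern == "Even",
            spread >= 1, noise_cv >= 0, level > 0)
  structure(list(pattern = pattern, n_genes = as.integer(n_genes),
                 margin = margin, spread = spread, noise_cv = noise_cv,
                 level = level),
            class = "PlantSpec")
}

# Values (normalized scale) for one planted gene. Enriched block sits at
# level*spread*margin..level*spread*margin*spread, non-enriched at
# level..level*spread, so the decision ratio is exactly `margin`. Gradient is
# a geometric ladder with max/min = margin. Within-block multipliers are
# randomly assigned to samples (RNG state is the caller's responsibility).
plant_gene_values <- function(spec, sample_ids) {
  n <- length(sample_ids)
  spread_steps <- function(k, spread) {
    if (k == 1L) 1 else spread^((seq_len(k) - 1L) / (k - 1L))
  }
  if (spec$pattern == "Even") {
    v <- spec$level * sample(spread_steps(n, spec$spread))
  } else if (spec$pattern == "Gradient") {
    v <- spec$level * sample(spec$margin^((seq_len(n) - 1L) / (n - 1L)))
  } else {
    members <- strsplit(spec$pattern, "&", fixed = TRUE)[[1L]]
    idx <- match(members, sample_ids)
    if (anyNA(idx)) {
      stop("pattern '", spec$pattern, "' names unknown sample(s)",
           call. = FALSE)
    }
    k <- length(idx)
    v <- numeric(n)
    v[-idx] <- spec$level * sample(spread_steps(n - k, spec$spread))
    v[idx] <- spec$level * spec$spread * spec$margin *
      sample(spread_steps(k, spec$spread))
  }
  if (spec$noise_cv > 0) {
    sigma <- sqrt(log(1 + spec$noise_cv^2))
    v <- v * exp(stats::rnorm(n, -sigma^2 / 2, sigma))
  }
  v
}

check_plant_spec <- function(spec, sample_ids, t_design) {
  n <- length(sample_ids)
  if (spec$spread >= t_design) {
    stop("inconsistent plant: within-block spread ", spec$spread,
         " >= design threshold ", t_design, call. = FALSE)
  }
  if (spec$pattern == "Gradient") {
    if (spec$margin < t_design) {
      stop("inconsistent Gradient plant: margin ", spec$margin,
           " below design threshold ", t_design, call. = FALSE)
    }
    if (spec$margin^(1 / (n - 1L)) >= t_design) {
      stop("inconsistent Gradient plant: step ratio ",
           signif(spec$margin^(1 / (n - 1L)), 4), " >= design threshold",
           call. = FALSE)
    }
  } else if (spec$pattern != "Even") {
    members <- strsplit(spec$pattern, "&", fixed = TRUE)[[1L]]
    if (!length(members) || length(members) >= n ||
        !all(members %in% sample_ids)) {
      stop("pattern '", spec$pattern,
           "' is not a proper non-empty subset of the samples", call. = FALSE)
    }
    if (spec$margin < t_design) {
      stop("inconsistent enriched plant: margin ", spec$margin,
           " below design threshold ", t_design, call. = FALSE)
    }
  }
  invisible(spec)
}

#' Map a designed (normalized-scale) matrix back to raw scale
#'
#' Subtracts the pseudocount, adds a near-flat ballast gene so every column of
#' the pre-pseudocount matrix sums exactly to `config$target_total`, and
#' multiplies each sample by a random positive scale factor (mimicking
#' library-size differences; `prepare_matrix()` must undo them exactly).
#' By construction `prepare_matrix()` applied to the result reproduces
#' `final_values` (plus the ballast row) to floating-point accuracy.
#'
#' @param final_values designed matrix on the normalized scale (all entries >
#'   `config$pseudocount`), genes x samples with dimnames.
#' @param config a [preprocess_config()].
#' @param sample_scales logical: distort raw columns by random scale factors?
#' @param t_design design threshold; the ballast row's max/min spread must
#'   stay below it (error otherwise — lower the plant levels).
#' @param ballast_id gene ID for the ballast row.
#' @return list with `raw` (an [expression_table()]), `ballast_id`,
#'   `scale_factors`.
#' @export
assemble_raw <- function(final_values, config = preprocess_config(),
                         sample_scales = TRUE, t_design = 2.5,
                         ballast_id = "ballast_even") {
  u <- final_values - config$pseudocount
  if (any(u <= 0)) {
    stop("designed values must exceed the pseudocount", call. = FALSE)
  }
  ballast <- config$target_total - colSums(u)
  if (any(ballast <= 0)) {
    stop("planted columns exceed target_total; lower plant levels or n_genes",
         call. = FALSE)
  }
  if (max(ballast) / min(ballast) >= t_design) {
    stop("ballast row would not be Even (spread ",
         signif(max(ballast) / min(ballast), 4),
         "); lower plant levels so columns are better balanced",
         call. = FALSE)
  }
  u <- rbind(u, matrix(ballast, 1L, dimnames = list(ballast_id)))
  k <- if (sample_scales) {
    exp(stats::runif(ncol(u), log(0.2), log(5)))
  } else {
    rep(1, ncol(u))
  }
  raw <- sweep(u, 2L, k, `*`)
  list(raw = expression_table(raw, normalized = FALSE),
       ballast_id = ballast_id, scale_factors = k)
}

#' Generate a raw matrix with planted ground truth
#'
#' Builds a raw-scale expression matrix from a list of [plant_spec()]s such
#' that `classify_matrix(prepare_matrix(raw), t_design)` recovers every
#' planted category exactly when `noise_cv = 0`. A ballast gene (truth
#' `"Even"`) balances the column totals; random per-sample scale factors
#' exercise the normalization's scale invariance.
#'
#' @param specs list of [plant_spec()]s.
#' @param sample_ids ordered sample IDs.
#' @param t_design design threshold (plants are validated against it when
#'   `strict = TRUE`; see [plant_spec()]).
#' @param seed integer seed; the generator is deterministic given
#'   `specs` + `seed`.
#' @param config a [preprocess_config()].
#' @param sample_scales distort raw columns by random scale factors?
#' @param strict validate recoverability (margins >= `t_design`, spreads
#'   below it)? Turn off to plant sub-threshold margins deliberately, e.g.
#'   for calibration fixtures.
#' @param id_prefix prefix for generated gene IDs.
#' @return list with `raw` (an [expression_table()]), `truth` (data.frame
#'   `gene_id`, `pattern` — ballast included), `scale_factors`.
#' @export
generate_matrix <- function(specs, sample_ids, t_design = 2.5, seed = 1L,
                            config = preprocess_config(),
                            sample_scales = TRUE, strict = TRUE,
                            id_prefix = "g") {
  if (inherits(specs, "PlantSpec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L, length(sample_ids) >= 2L)
  check_threshold(t_design)
  if (strict) {
    for (spec in specs) check_plant_spec(spec, sample_ids, t_design)
  }
  n_total <- sum(vapply(specs, `[[`, integer(1), "n_genes"))
  with_local_seed(seed, {
    final <- matrix(NA_real_, n_total, length(sample_ids),
                    dimnames = list(NULL, sample_ids))
    truth_pattern <- character(n_total)
    row <- 0L
    for (spec in specs) {
      for (i in seq_len(spec$n_genes)) {
        row <- row + 1L
        final[row, ] <- plant_gene_values(spec, sample_ids)
        truth_pattern[row] <- spec$pattern
      }
    }
    rownames(final) <- sprintf("%s%05d", id_prefix, seq_len(n_total))
    # extreme noisy draws are floored just above the pseudocount so the
    # designed matrix stays mappable to a non-negative raw scale
    final <- pmax(final, config$pseudocount + 0.01)
    asm <- assemble_raw(final, config,
                        sample_scales = sample_scales, t_design = t_design)
  })
  truth <- data.frame(
    gene_id = c(rownames(final), asm$ballast_id),
    pattern = c(truth_pattern, "Even"),
    stringsAsFactors = FALSE
  )
  list(raw = asm$raw, truth = truth, scale_factors = asm$scale_factors)
}

#' Generate housekeeping-like negative controls
#'
#' Each gene is flat at `level` except one random sample multiplied by a
#' factor drawn log-uniformly from `[1, spread]`. After the pipeline the gene
#' is classified single-sample enriched exactly when its factor is at least
#' the threshold, so the expected false positive rate at threshold `T` is
#' `max(0, 1 - log(T)/log(spread))` — zero whenever `spread < T`.
#'
#' @param n number of genes (>= 1).
#' @param spread upper bound of the spike factor (>= 1).
#' @param sample_ids ordered sample IDs.
#' @param seed integer seed.
#' @param level baseline value on the normalized scale.
#' @param id_prefix gene-ID prefix.
#' @return list with `final` (designed normalized-scale block), `gene_ids`,
#'   `multipliers` (the drawn spike factors), `p_exceed` (function of `T`
#'   giving the expected enriched fraction).
#' @export
generate_housekeeping_like <- function(n, spread, sample_ids, seed = 1L,
                                       level = 200, id_prefix = "hk") {
  if (!is.numeric(n) || length(n) != 1L || n < 1L) {
    stop("n must be a positive integer", call. = FALSE)
  }
  stopifnot(spread >= 1, length(sample_ids) >= 2L)
  with_local_seed(seed, {
    mult <- exp(stats::runif(n, 0, log(spread)))
    spike_at <- sample.int(length(sample_ids), n, replace = TRUE)
  })
  final <- matrix(level, n, length(sample_ids),
                  dimnames = list(sprintf("%s%05d", id_prefix, seq_len(n)),
                                  sample_ids))
  final[cbind(seq_len(n), spike_at)] <- level * mult
  list(final = final,
       gene_ids = rownames(final),
       multipliers = mult,
       p_exceed = function(T) {
         if (spread <= 1) return(0)
         max(0, 1 - log(T) / log(spread))
       })
}

#' Generate an isoform tracking table with planted switch structure
#'
#' Builds isoform-level plants (one category per isoform) and emits them as a
#' long-format tracking table, optionally with non-OK rows that aggregation
#' must ignore. The archetype is a receptor-like gene whose exon-inclusion
#' isoform is enriched early and whose exon-skipping isoform emerges in the
#' specified lineages.
#'
#' @param plan named list: gene ID -> character vector of per-isoform
#'   categories (`"Even"`, `"Gradient"`, or canonical enriched strings).
#' @param sample_ids ordered sample IDs.
#' @param seed integer seed.
#' @param t_design design threshold.
#' @param margin,spread,level plant parameters, see [plant_spec()].
#' @param add_non_ok also emit a `LOWDATA` row (per sample) for the first
#'   gene, with large FPKM that must not leak into aggregates?
#' @return list with `iso` (an [isoform_table()]), `truth` (data.frame
#'   `isoform_id`, `gene_id`, `pattern`), `scale_factors`.
#' @export
generate_isoform_table <- function(plan, sample_ids, seed = 1L,
                                   t_design = 2.5, margin = 4, spread = 1.1,
                                   level = 100, add_non_ok = TRUE) {
  stopifnot(is.list(plan), length(plan) >= 1L, !is.null(names(plan)))
  config <- preprocess_config()
  iso_ids <- unlist(lapply(names(plan), function(g) {
    sprintf("%s.iso%d", g, seq_along(plan[[g]]))
  }), use.names = FALSE)
  gene_of <- rep(names(plan), lengths(plan))
  categories <- unlist(plan, use.names = FALSE)
  with_local_seed(seed, {
    final <- matrix(NA_real_, length(iso_ids), length(sample_ids),
                    dimnames = list(iso_ids, sample_ids))
    for (i in seq_along(iso_ids)) {
      spec <- plant_spec(categories[i], 1L, margin = margin, spread = spread,
                         level = level)
      check_plant_spec(spec, sample_ids, t_design)
      final[i, ] <- plant_gene_values(spec, sample_ids)
    }
    asm <- assemble_raw(final, config,
                        sample_scales = TRUE, t_design = t_design,
                        ballast_id = "ballast.iso1")
  })
  raw <- unclass(asm$raw)
  rows <- expand.grid(isoform_id = rownames(raw), sample_id = sample_ids,
                      stringsAsFactors = FALSE)
  rows$gene_id <- c(gene_of, "ballast")[match(rows$isoform_id, rownames(raw))]
  rows$fpkm <- raw[cbind(rows$isoform_id, rows$sample_id)]
  rows$status <- "OK"
  if (add_non_ok) {
    decoy <- data.frame(
      isoform_id = sprintf("%s.isoX", names(plan)[1L]),
      sample_id = sample_ids,
      gene_id = names(plan)[1L],
      fpkm = 10 * max(raw),
      status = "LOWDATA",
      stringsAsFactors = FALSE
    )
    rows <- rbind(rows, decoy)
  }
  truth <- data.frame(
    isoform_id = c(iso_ids, "ballast.iso1"),
    gene_id = c(gene_of, "ballast"),
    pattern = c(categories, "Even"),
    stringsAsFactors = FALSE
  )
  list(iso = isoform_table(rows$isoform_id, rows$gene_id, rows$sample_id,
                           rows$fpkm, rows$status),
       truth = truth, scale_factors = asm$scale_factors)
}

# Largest-remainder allocation of `total` items proportional to `weights`.
allocate_counts <- function(total, weights) {
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Log-uniform draws strictly inside (lo, hi), nudged off the bin edges so a
# drawn decision ratio never collides with a classification threshold.
runif_log_bin <- function(n, lo, hi) {
  if (n == 0L) return(numeric(0))
  exp(stats::runif(n, log(lo * 1.001), log(hi * 0.999)))
}

#' Generate the default five-state synthetic study
#'
#' A full study emulating the structure of a five-state cardiovascular
#' differentiation experiment (ES, MCP, CM, SM, EC): a main gene population
#' with the published composition — 48% Even, 31% Gradient, and
#' lineage-enriched genes split 1680:1560 between single- and multi-lineage
#' categories (scaled to `n_genes`, default one tenth of the published 15132)
#' with the multi-lineage genes concentrated in ES&MCP, ES&MCP&CM, SM&EC and
#' CM&SM&EC — plus housekeeping-like negative controls whose spike factors
#' reproduce the published false positive rates at thresholds 1.5/2/2.5/3
#' (36.8%, 10.2%, 3.5%, 1.9%) and 49 positive controls whose margins
#' reproduce the published false negative rates (0%, 0%, ~4%, ~16%).
#'
#' @param seed integer seed.
#' @param sample_ids ordered sample IDs (default the five cell states).
#' @param n_genes size of the main population (default 1513).
#' @param n_negatives number of housekeeping-like controls (default 1000).
#' @param n_positives number of positive controls (default 49).
#' @param t_design design threshold (default 2.5).
#' @param config a [preprocess_config()].
#' @return list with `raw`, `truth` (gene_id, pattern, block), `negatives`,
#'   `positives` (control [gene_list()]s), `expected_fpr`, `expected_fnr`
#'   (exact fractions at thresholds 1.5, 2, 2.5, 3, computed from the drawn
#'   margins), `sample_ids`, `t_design`.
#' @export
generate_study <- function(seed = 1L,
                           sample_ids = c("ES", "MCP", "CM", "SM", "EC"),
                           n_genes = 1513L, n_negatives = 1000L,
                           n_positives = 49L, t_design = 2.5,
                           config = preprocess_config()) {
  stopifnot(length(sample_ids) == 5L)
  grid <- c(1.5, 2, 2.5, 3)
  n_single <- round(n_genes * 1680 / 15132)
  n_multi <- round(n_genes * 1560 / 15132)
  n_even <- round(n_genes * 0.48)
  n_gradient <- n_genes - n_single - n_multi - n_even
  stopifnot(n_gradient > 0)

  singles <- enumerate_categories(sample_ids, FALSE)
  singles <- singles[n_samples_in_category(singles) == 1L]
  multis <- enumerate_categories(sample_ids, FALSE)
  multis <- multis[n_samples_in_category(multis) > 1L]
  favored <- c(paste(sample_ids[1:2], collapse = "&"),
               paste(sample_ids[1:3], collapse = "&"),
               paste(sample_ids[4:5], collapse = "&"),
               paste(sample_ids[3:5], collapse = "&"))
  multi_w <- ifelse(multis %in% favored, 8, 1)

  # housekeeping spike-factor bins: fraction at or above each threshold
  # equals the published FPR ladder exactly (368/102/35/19 per 1000)
  neg_bin_frac <- c(0.632, 0.266, 0.067, 0.016, 0.019)
  neg_bin_lo <- c(1.0, 1.5, 2.0, 2.5, 3.0)
  neg_bin_hi <- c(1.5, 2.0, 2.5, 3.0, 5.0)
  # positive-control margin bins: miss nothing below 2.5, ~4% at 2.5, ~16% at 3
  pos_bin_frac <- c(0.043, 0.124, 0.833)
  pos_bin_lo <- c(2.0, 2.5, 3.0)
  pos_bin_hi <- c(2.5, 3.0, 6.0)

  with_local_seed(seed, {
    final_rows <- list()
    truth_rows <- list()
    add_block <- function(final, patterns, block) {
      final_rows[[length(final_rows) + 1L]] <<- final
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        gene_id = rownames(final), pattern = patterns, block = block,
        stringsAsFactors = FALSE)
    }

    plant_block <- function(patterns, margins, spreads, level, prefix) {
      final <- matrix(NA_real_, length(patterns), length(sample_ids),
                      dimnames = list(sprintf("%s%05d", prefix,
                                              seq_along(patterns)),
                                      sample_ids))
      for (i in seq_along(patterns)) {
        spec <- plant_spec(patterns[i], 1L, margin = margins[i],
                           spread = spreads[i], level = level)
        final[i, ] <- plant_gene_values(spec, sample_ids)
      }
      final
    }

    # main population
    single_counts <- allocate_counts(n_single, rep(1, length(singles)))
    multi_counts <- allocate_counts(n_multi, multi_w)
    main_patterns <- c(rep(singles, single_counts),
                       rep(multis, multi_counts),
                       rep("Even", n_even), rep("Gradient", n_gradient))
    n_main <- length(main_patterns)
    is_grad <- main_patterns == "Gradient"
    margins <- runif_log_bin(n_main, t_design * 1.05, 8)
    # gradient ladders need step ratio below every grid threshold
    margins[is_grad] <- runif_log_bin(sum(is_grad), t_design * 1.05, 5)
    spreads <- exp(stats::runif(n_main, 0, log(1.35)))
    add_block(plant_block(main_patterns, margins, spreads,
                          level = 80, prefix = "gene"),
              main_patterns, "main")

    # housekeeping-like negatives: exact bin counts, spike in a random sample
    neg_counts <- allocate_counts(n_negatives, neg_bin_frac)
    neg_mult <- unlist(mapply(runif_log_bin, neg_counts, neg_bin_lo,
                              neg_bin_hi, SIMPLIFY = FALSE))
    neg_final <- matrix(150, n_negatives, length(sample_ids),
                        dimnames = list(sprintf("hk%05d",
                                                seq_len(n_negatives)),
                                        sample_ids))
    spike_at <- sample.int(length(sample_ids), n_negatives, replace = TRUE)
    neg_final[cbind(seq_len(n_negatives), spike_at)] <- 150 * neg_mult
    neg_truth <- ifelse(neg_mult >= t_design,
                        sample_ids[spike_at], "Even")
    add_block(neg_final, neg_truth, "negative_control")

    # positive controls: single-lineage spikes in ES or CM
    pos_counts <- allocate_counts(n_positives, pos_bin_frac)
    pos_margin <- unlist(mapply(runif_log_bin, pos_counts, pos_bin_lo,
                                pos_bin_hi, SIMPLIFY = FALSE))
    pos_margin <- sample(pos_margin)
    pos_lineage <- sample(sample_ids[c(1L, 3L)], n_positives, replace = TRUE)
    pos_final <- matrix(150, n_positives, length(sample_ids),
                        dimnames = list(sprintf("pos%03d",
                                                seq_len(n_positives)),
                                        sample_ids))
    pos_final[cbind(seq_len(n_positives),
                    match(pos_lineage, sample_ids))] <- 150 * pos_margin
    # truth at the design threshold: sub-margin controls are designed misses
    add_block(pos_final,
              ifelse(pos_margin >= t_design, pos_lineage, "Even"),
              "positive_control")

    final <- do.call(rbind, final_rows)
    asm <- assemble_raw(final, config,
                        sample_scales = TRUE, t_design = t_design)
  })
  truth <- do.call(rbind, truth_rows)
  truth <- rbind(truth, data.frame(gene_id = asm$ballast_id,
                                   pattern = "Even", block = "ballast",
                                   stringsAsFactors = FALSE))
  neg_ids <- truth$gene_id[truth$block == "negative_control"]
  pos_ids <- truth$gene_id[truth$block == "positive_control"]
  list(
    raw = asm$raw,
    truth = truth,
    negatives = gene_list(neg_ids, "negative_control"),
    positives = gene_list(pos_ids, "positive_control"),
    expected_fpr = vapply(grid, function(t) mean(neg_mult >= t), numeric(1)),
    expected_fnr = vapply(grid, function(t) mean(pos_margin < t), numeric(1)),
    threshold_grid = grid,
    sample_ids = sample_ids,
    t_design = t_design,
    scale_factors = asm$scale_factors
  )
}
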