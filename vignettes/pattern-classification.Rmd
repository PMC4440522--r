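---
title: "Deterministic expression-pattern classification across cell states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic expression-pattern classification across cell states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gepa)
```

## The model

`gepa` answers a multi-state question — *in which subset of cell states is
this gene enriched?* — with a deterministic rule rather than a statistical
test. For one gene with strictly positive normalized values across `N >= 2`
states and a fold-change threshold `T > 1`:

1. sort the values in descending order;
2. scan consecutive sorted ratios from the top and stop at the first one
   `>= T`: the states above the cut are the gene's enriched pattern;
3. if no consecutive ratio reaches `T`, assign `Even` when the overall
   max/min ratio is `< T`, otherwise `Gradient`.

The rule partitions genes into `2^N - 2` enriched categories (every proper
non-empty state subset) plus the two sentinels — 32 categories for five
states. It is invariant under scaling a gene's whole vector, equivariant
under permuting states, and monotone in `T`: raising the threshold can only
move genes out of enriched categories and into `Even`. For `N = 2` the
`Gradient` category is unreachable, since the only consecutive ratio *is*
max/min. These properties are asserted as tests.

The rule's simplicity is deliberate: no between-gene comparison, no
replicate requirement, no distributional assumption, one interpretable
parameter. The cost is that it has no error model — which is why threshold
calibration against control gene lists (below) is part of the package
rather than an afterthought.

## Preprocessing

The classifier requires strictly positive values; `prepare_matrix()`
produces them in a fixed order:

1. **Isoform aggregation** (isoform input only): a gene's FPKM per sample is
   the sum over its isoforms with quality status `"OK"` (token configurable
   via `preprocess_config(ok_status=)`). Non-OK rows are kept by the reader
   but never aggregated; a gene whose isoforms are all non-OK in a sample
   contributes 0 there.
2. **All-zero filtering**: genes that are 0 in every sample are removed.
   Genes with any positive value are kept — the removal rule speaks only of
   all-zero genes.
3. **Per-sample normalization**: each sample is scaled so its total equals
   `target_total` (default 1e6). This happens *after* filtering because
   filtering changes column sums; the order is pinned and tested.
4. **Pseudocount**: a constant (default 1) is added last, so every value is
   at least the pseudocount and every fold change is defined. Adding it
   after scaling means low-abundance genes have fold changes shrunk toward
   1, which stabilizes them against the threshold; two genes at 3 vs 0 raw
   FPKM do not become "infinitely enriched".

Normalization makes the pipeline invariant to per-sample library-size
factors: multiplying one sample's raw column by any positive constant leaves
the prepared matrix, and hence every classification, unchanged.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 2.5 | fold change that defines an enrichment cut (unitless ratio of normalized values) |
| `target_total` | 1e6 | per-sample total after normalization |
| `pseudocount` | 1 | constant added after scaling |
| `ok_status` | `"OK"` | isoform quality token counted as usable |

The default threshold of 2.5 is the operating point selected by the
calibration procedure on this kind of five-state data: sweeping
`{1.5, 2, 2.5, 3}`, false positives on housekeeping controls fall steeply up
to 2.5 while false negatives on marker-gene controls only rise sharply
beyond it, so 2.5 minimizes their sum. `threshold_sweep()` recomputes this
trade-off for any dataset; the default is a starting point, not a constant
of nature.

## Numerical choices

* **Comparisons are exact.** The cut condition is `ratio >= T` with no
  epsilon; an epsilon would silently move genes between categories. The
  pseudocount guarantees finite ratios.
* **Even/Gradient boundary**: max/min exactly equal to `T` is `Gradient` —
  `Even` requires the span to be strictly smaller than the threshold.
* **Ties** in the descending sort are broken stably by the user-supplied
  sample order. A tie (ratio 1) can never trigger a cut, so tie-breaking
  only fixes the reported `sorted_sample_order`, never the category.
* **Category strings** are canonical: enriched states joined by `&` in the
  user-supplied sample order (`ES&MCP&CM`), not in descending-expression
  order, so one subset always maps to one key.
* **On-disk round trips** print doubles with `%.17g`, so write-then-read
  reproduces a matrix or pattern table bit-for-bit.
* **Degenerate inputs** fail loudly: non-positive values at classification
  time, zero column sums at normalization, empty gene lists, unknown IDs —
  each error names the offender.

## Calibration and the null control

False positive rate: the fraction of housekeeping (negative-control) genes
receiving *any* enriched pattern — `Even` and `Gradient` are both correct
for a control. False negative rate: the fraction of positive-control genes
receiving *no* enriched pattern. A positive is "captured" by any enriched
category by default, not only its biologically expected lineage; an
expected-lineage strict mode exists (`false_negative_rate(strict = TRUE)`)
but is off by default, since capture-by-any-pattern is the weaker and more
defensible claim. Denominators are controls actually present in the matrix;
absent IDs are reported separately and never dilute a rate. Rates are exact
fractions `k/n`, serialized unrounded alongside a 0.1%-rounded copy.

`shuffle_matrix()` provides the null: `"global"` mode permutes all values
across the whole matrix and is the default, because it is the only mode that
can destroy the enrichment structure. `"within_gene"` mode permutes each
gene's values across states — this conserves every gene's value multiset,
hence its sorted ratio profile, so its enriched-vs-not status is *exactly*
invariant; only the identity of the enriched states moves. The contrast
between the two modes is itself a property test: structure collapses under
global shuffling and provably cannot under within-gene shuffling.

## The synthetic generators

Because the rule is deterministic, fixtures with exact ground truth are
constructible, and the package treats their generator as first-class tested
code.

Plants are designed on the *post-normalization* scale: an enriched gene gets
a low block at `level..level*spread`, an enriched block
`margin`-fold above it, so `margin` is precisely the fold change the
classifier sees at the decision cut; `Gradient` genes are geometric ladders
with max/min equal to `margin` and steps below the design threshold. The
designed matrix is then mapped back to raw scale by subtracting the
pseudocount, adding a single near-flat *ballast* gene that makes every
column of the pre-pseudocount matrix sum exactly to `target_total`, and
multiplying each column by a random library-size factor. `prepare_matrix()`
provably inverts this construction to floating-point accuracy, so noise-free
plants with `margin >= T` are recovered with 100% accuracy — and the same
fixture exercises normalization's scale invariance for free. Noise, when
requested, is multiplicative log-normal parameterized by a coefficient of
variation: simple, positive, scale-free.

`generate_study()` bundles the default five-state study the package's
reference numbers are computed on: 1513 main genes composed of 48% `Even`,
~31% `Gradient`, 168 single-lineage and 156 multi-lineage genes (the
multi-lineage mass concentrated in `ES&MCP`, `ES&MCP&CM`, `SM&EC`,
`CM&SM&EC`, as expected when adjacent differentiation stages share
programs); 1000 housekeeping-like negatives whose spike factors are drawn
from fixed bins so that exactly 36.8% / 10.2% / 3.5% / 1.9% of them exceed
thresholds 1.5 / 2 / 2.5 / 3; and 49 positive controls with margins binned
to miss nothing below 2.5, ~4% at 2.5 and ~16% at 3. These defaults emulate
the scale and error structure of a real five-state cardiovascular
differentiation experiment at one-tenth gene count; they were fixed once as
the study conditions and the acceptance script recomputes everything from
them at run time.

What the generator does **not** emulate: count-level sampling noise,
gene-length and GC bias, correlated co-expression modules, batch structure,
or quantification uncertainty. Passing tests on these fixtures demonstrate
the algorithm's correctness and the pipeline's invariances, not robustness
to every artifact of real RNA-seq.

## Problem sizes

The test suite checks the scan against an independent brute-force rule on
100,000 random vectors (5,000 per combination of `N = 2..6` and
`T ∈ {1.5, 2, 2.5, 3}`), recovers all 32 planted categories at 3 genes per
enriched category, and runs the shuffle null over 20 seeds on a 451-gene
structured matrix; the acceptance script uses the full default study (2,563
genes including controls). These sizes were chosen to exercise every code
path with comfortable statistical margins while keeping a full run in tens
of seconds.

## Limitations

* The rule reports patterns, not significance; with replicates available, a
  variance-aware method is complementary, not competing.
* A single threshold is shared by all genes; genes near the threshold flip
  categories under small perturbations (the calibration sweep quantifies
  how many).
* Isoform-level classification normalizes over the isoform matrix itself
  rather than inheriting gene totals, a documented choice; exon-level
  read-stack analysis is out of scope.
* lncRNA (or any biotype) screens rely on a user-supplied annotation list;
  the package does not ship annotations.
* Reproducing the originally distributed five-state dataset requires files
  that are not redistributable here; `reproduce_published_run()` computes
  all headline quantities once they are supplied.
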