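# gerosig

Cross-cohort meta-analysis of geroprotective transcriptomic signatures.

## The problem

Several very different interventions extend healthspan in mice — ablation of
senescent cells (senolysis), long-term caloric restriction, in vivo partial
OSKM reprogramming, and heterochronic parabiosis. Do they act through a
shared molecular program? `gerosig` implements a reusable pipeline for
answering that question from differential-expression (DEG) tables: it
quantifies whether geroprotective interventions (GIs) share a
gene-expression and pathway signature that is *inverse* to the signature of
normal aging, whether young-animal chronic-inflammation (CI) disease models
recapitulate that aging signature, and whether a linear transcriptomic aging
clock moves accordingly. It is aimed at computational biologists doing
signature-level meta-analysis across studies, organs and cell types, where
only per-contrast DEG statistics (not raw counts) are comparable.

## What it computes

Each *context* (study × contrast × organ-or-cell-type) contributes a
signature table of per-gene statistics (log2 fold-change, p, BH-adjusted p).
The pipeline stages are:

* **DEG selection** — a gene is a DEG iff |FC| > 1.25 (linear scale) and
  BH-adjusted p < 0.05, both strict.
* **Signature correlation** — for every pair of contexts, Spearman's rho of
  the log2 fold-changes over the DEGs *shared* by both
  (rho = 1 − 6Σd²/(n(n²−1)) on average ranks); pairs sharing < 10 DEGs are
  excluded, and coefficients are masked for presentation unless p < 0.05
  (exact permutation p for n ≤ 10, t-approximation above).
* **Trend convergence** — direction-specific DEG sets per intervention with
  context-count rules (≥ 1 organ for senolysis, ≥ 2 for caloric restriction
  and reprogramming, ≥ 3 cell types for parabiosis), intersected across the
  two opposing trends (GI-up ∩ Y-Par-down ∩ aging-down, and vice versa);
  genes in ≥ k = 3 of the six sets form the convergent signature.
* **Over-representation and rank scores** — upper-tail hypergeometric ORA of
  each DEG list against a GMT library (reported iff overlap ≥ 2, p < 0.01,
  fold enrichment ≥ 1.5), then weighted pathway rank scores across contexts:
  each whole-organ hit at FDR < 0.01 scores 1 point, each parabiosis
  cell-type hit 0.5 points; trend score tables are Spearman-correlated.
* **Chronic-inflammation score maps** — per gene/pathway, signed context
  counts (+1 up, −1 down) split into bulk and single-cell axes, with the
  convergent GI genes overlaid.
* **Single-cell DEG hygiene** — genes prefiltered to > 1% of cells and > 5
  cells with > 1 UMI; a DEG is excluded as probable ambient RNA iff it is
  both a top-5 marker of *another* cell type and among the top-50 most
  highly expressed genes of the dataset.
* **Transcriptomic clock** — a linear clock (age = intercept + Σ βᵍ ·
  log2(FPKM + 1)) applied cross-species: mouse symbols mapped to human
  homologs (collisions summed), gene lengths forced to 10 kb for UMI
  matrices, readouts scaled per panel and compared between groups with an
  exact rank-sum test.

A synthetic-data module plants a signed aging program (reversed by GIs,
recapitulated by Y-Par and CI models), calibrated null p-values, enriched
gene sets, ambient contaminants and an invertible linear clock, so every
stage has a recovery test against known truth.

## Worked example

```r
library(gerosig)
d <- tempfile()
res <- run_synthetic_study(d, config = list(seed = 1))
#> read 28 signature tables (1000 genes each on average)
#> ambient filter: excluded 20 DEG entries across single-cell contexts
#> correlation: 231 pairs, 0 excluded below 10 shared DEGs
#> convergence: 81 genes shared by >= 3 sets
#> enrichment: 168 significant rows; aging-up vs GI-down score rho = 1.000
#> chronic-inflammation maps: 93 genes scored
#> clock: 12 samples aged; 1 panel comparisons

blocks <- read.delim(file.path(d, "results", "correlation_blocks.tsv"))
blocks[, c("block_a","block_b","n_pairs","mean_rho","n_significant","frac_negative")]
#>   block_a block_b n_pairs mean_rho n_significant frac_negative
#> 1   AGING   AGING      28    0.995            28             0
#> 2   AGING      GI      80   -0.994            80             1
#> 3   AGING    YPAR      32    0.995            32             0
#> 4      GI      GI      45    0.994            45             0
#> 5      GI    YPAR      40   -0.995            40             1
#> 6    YPAR    YPAR       6    0.996             6             0
```

Reading the block table: aging signatures correlate with each other across
organs (mean rho 0.995), intervention signatures correlate with each other
(0.994), and every significant intervention × aging pair is negative
(mean −0.994) — the planted structure in which interventions reverse the
aging program, recovered end to end. The young parabiont (YPAR) behaves
like an aging signature, anticorrelating with the interventions. The run
directory also contains the trend-membership and shared-gene reports, the
enrichment and rank-score tables, the CI score maps with the convergent
genes overlaid, per-sample clock ages, and `summary.json`.

Individual stages are exported (`select_degs()`, `correlation_matrix()`,
`trend_intersection()`, `ora_test()`, `pathway_rank_scores()`,
`ci_gene_scores()`, `filter_ambient_degs()`, `apply_clock()`, ...) and
operate on plain files: tab-separated signature tables and manifests,
standard GMT gene sets, two-column homolog maps, dense or MatrixMarket
count matrices.

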