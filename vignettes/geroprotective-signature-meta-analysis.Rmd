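---
title: "Meta-analysis of geroprotective transcriptomic signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of geroprotective transcriptomic signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gerosig)
```

## Scope and model of the data

`gerosig` operates at the level of differential-expression *signatures*: for
each context — a study, a contrast (e.g. treated vs aged control, old vs
young), and an organ or cell type — the input is a table of per-gene log2
fold-changes with raw and BH-adjusted p-values. The package deliberately
does **not** fit differential-expression models: cross-study comparability
at the raw-count level is poor, while signature-level statistics (published
or re-derived with DESeq2/MAST upstream) are the common currency of
cross-cohort aging meta-analyses. Externally supplied adjusted p-values are
therefore trusted as-is; only a missing `fdr` column triggers internal BH
adjustment.

Contexts carry a `role` describing their position in the design: `GI` for a
geroprotective-intervention contrast (including the old heterochronic
parabiont), `AGING` for an old-vs-young reference, `YPAR` for the young
heterochronic parabiont (whose signature *recapitulates* aging — the young
animal is pushed toward the old state), and `CI` for chronic-inflammation
disease models in young animals.

## DEG selection

A gene is a DEG iff `2^|log2fc| > 1.25` and `fdr < 0.05`. Both are strict
inequalities: the thresholds are quoted as strict bounds, and the boundary
behaviour (a linear fold-change of exactly 1.25 is *not* selected) is fixed
and tested rather than left to floating-point accident. The fold-change
bound is applied on the linear scale; `|log2fc| > log2(1.25)` is the same
rule, and a reader flag converts linear-fold-change input dialects at read
time. Gene symbols are case-sensitive by default, with an opt-in uppercase
normalization for cross-species tables where symbol casing differs
systematically (mouse `Cat` vs human `CAT`).

## Pairwise signature correlation

For every unordered pair of contexts the fold-changes of the *shared* DEGs
— genes passing the DEG rule in **both** contexts, any direction — are
Spearman-correlated with average ranks under ties. "Shared" is read as the
intersection of each context's own DEG set; a union or one-sided reading
would correlate genes that are noise in one of the two tables.

Two numerical choices matter:

* **P-values.** For n ≤ 10 shared DEGs the two-sided p-value is computed by
  full permutation enumeration (the n! permutations are generated once and
  evaluated vectorised; because permutation preserves the rank multisets,
  rho is affine in the permuted rank inner product). Above n = 10 the
  t-approximation `t = rho sqrt((n-2)/(1-rho^2))` is used. The boundary sits
  where exactness is affordable; pairs near it are rare because pairs with
  fewer than 10 shared DEGs are excluded outright. Whether the original
  analyses used one- or two-sided p-values is not stated; two-sided is
  adopted.
* **Exclusion and masking are different things.** Pairs with fewer than 10
  shared DEGs get no coefficient at all, but their shared-DEG count is
  retained so exclusions remain auditable. Pairs with a coefficient but
  p ≥ 0.05 keep the coefficient and are only masked for presentation. No
  multiple-testing correction is applied across pairs — masking is at the
  raw p, matching the presentation rule the pipeline reproduces.

All pairs are computed, including self-study aging references against their
own intervention contexts; `block_summary()` aggregates the matrix by any
context field (typically role) into mean rho and sign fractions among
significant entries.

## Trend convergence

Each intervention contributes direction-specific DEG sets under its own
context-count rule: ≥ 1 organ (senolysis), ≥ 2 organs (caloric restriction,
reprogramming), ≥ 3 cell types (parabiosis; the same ≥ 3 rule is applied to
the young parabiont). A gene up in one organ and down in another counts
toward each direction independently — up- and down-sets are derived
separately, with no cancellation. The published global aging list enters as
a fixed signed input and is never recomputed.

The two opposing trends are then intersected: GI-up sets with the Y-Par
down-set and the downregulated aging genes, and the mirror image. Genes in
at least one set get a six-set membership vector; the convergent signature
is the genes in ≥ k = 3 sets. A gene qualifying under *both* trends is
contradictory data (e.g. up in one intervention's set and down in
another's); such genes are flagged in a `conflict` column and never
silently merged or dropped — how the original analysis resolved them is
unstated, so the package surfaces them.

## Over-representation and rank scores

ORA is the upper hypergeometric tail of the DEG-list/set overlap against
the library background. Three filters gate reporting: overlap ≥ 2,
p < 0.01, fold enrichment ≥ 1.5 (enrichment and overlap bounds inclusive —
they are "minimum" parameters — while the p cutoff is strict). The
background is the gene-set library's declared universe; in the pipeline the
library is built on the measured gene universe, which avoids
detection-bias inflation. BH FDR is computed within each (context,
direction) family across all tested sets, before the filters.

Rank scores aggregate hits across contexts: a pathway enriched at
FDR < 0.01 in a whole-organ (bulk) context scores 1 point, in a parabiosis
cell-type (single-cell) context 0.5 points — cell types within one organ
are not independent organs, hence the half weight. The weighting keys on
modality uniformly, including for single-cell aging contexts; the
alternative (raw hit counts for aging sets) is ambiguous in the source and
the weighted score is applied everywhere. FDR ties exactly at 0.01 do not
count (strict inequality). The two trend score tables are joined for
correlation on the union of scored items with absent items at 0; the
pipeline passes the full tested-set universe as the item domain, since with
strongly recovered planted sets the hits-only union can degenerate to
constant score vectors whose rank correlation is undefined.

Chronic-inflammation maps use signed scores: per gene, +1 for each CI
context where it is an up-DEG and −1 for each down, summed separately over
bulk organs and single-cell cell types (so scores are integers bounded by
the context counts); per pathway, the same signing over enrichment of the
up- and down-DEG lists. The convergent GI genes/pathways are overlaid with
their trend labels, with items absent from the map reported at 0 rather
than dropped.

## Single-cell DEG hygiene

Ambient RNA makes strong markers of abundant cell types look differentially
expressed everywhere. After model-based decontamination upstream (out of
scope here), the residual heuristic is a conjunction: a DEG of cell type c
is excluded iff it is among the top-5 markers of some *other* cell type
**and** among the top-50 most highly expressed genes of the dataset. Rank
bounds are inclusive ("among the top 5" includes rank 5). The marker
ranking is an injectable input — the upstream marker method is not
prescribed — and "most highly expressed" is computed on
library-size-normalized totals across all cells, since the rule speaks of
the dataset, not the cell type. Every exclusion records the offending cell
type and both ranks. The expression prefilter (> 1% of cells and > 5 cells
with > 1 UMI, strict) is provided for per-cell-type DEG testing upstream.

## Transcriptomic clock protocol

The clock is a linear model in transformed expression: age(s) = intercept +
Σᵍ βᵍ · log2(FPKMᵍₛ + 1). Coefficients are always an input file — trained
clock weights are external state, and the tests use synthetic clocks — so
the applier is generic. The cross-species protocol is: map mouse symbols to
human homologs (many-to-one collisions summed by default, conserving
counts; one-to-many sources take the first listed target; everything
logged), normalize counts by gene length and depth, and evaluate. For UMI
matrices every gene length is forced to 10,000 bases before normalization:
UMI counts carry no length bias, and the fixed length keeps them on the
clock's FPKM scale. Clock genes missing from a matrix impute to the
transform of zero abundance — conservative, and consistent with dropping
unmapped genes. Readout scaling ("scaled for presentation") has no stated
method; `scale_ages()` offers none/z-score/min-max per panel (z-score uses
the population standard deviation, so a two-sample panel scales to ±1) and
no default is claimed to match any published axis. Group comparison uses an
exact rank-sum test — panels are small, and the original test is unstated.

## The synthetic-data generator

The generator is first-class, tested code. It plants:

* a signed **aging program**: `n_program = 100` of `n_genes = 1000` genes
  with log2 effects ~ Normal(0, `effect_sd = 2`). The scale is chosen to
  emulate a *curated* aging signature — lists of globally consistent aging
  genes are dominated by strong movers (|log2FC| commonly 1–3), not by
  borderline-threshold genes. Roles map to sign multipliers: AGING, CI and
  YPAR express the program with +1, GIs with −1, OTHER with 0.
* **observed fold-changes** per context:
  `sign × effect + Normal(0, noise_sd/sqrt(n_samples_equiv))`, with
  `noise_sd = 0.2` and `n_samples_equiv = 4` (a typical murine group size)
  by default. P-values are the exact two-sided normal tails of that model,
  so null genes are uniformly calibrated at any group size and the FDR
  behaviour of downstream thresholds is testable. At `noise_sd = 0` every
  GI table is the exact negation of the AGING table on program genes.
* **gene sets**: planted sets draw half their members from the program,
  direction-specifically (alternating up/down sets), remainder and null
  sets uniform from the universe; the background is the full universe.
* a **marker/contaminant fixture** whose planted contaminants satisfy both
  ambient criteria exactly, with near-misses (foreign marker with low
  expression; highly expressed own marker) that must survive.
* an **invertible clock bed**: expression constructed by solving the linear
  model in transformed space per sample (signal distributed over same-sign
  coefficient genes, background genes absorbing the FPKM depth budget), so
  the noiseless protocol returns the target ages to machine precision;
  noise is added in transformed space.

The default study collection has 28 contexts: 2 organs each for senolysis,
caloric restriction and reprogramming, 4 bulk aging organs, 4 parabiosis
cell types × {old parabiont, young parabiont, single-cell aging}, and 3 CI
models at bulk and single-cell level — matching the 2–4 contexts per
intervention of the emulated design. What the generator does **not**
emulate: correlated noise between genes, inter-study batch structure,
heavy-tailed effect distributions, read- or UMI-level single-cell noise,
and the ambient-contamination process itself (only its downstream
signature). Passing recovery tests therefore demonstrate that the pipeline
recovers planted structure under calibrated independent noise — they do not
certify behaviour under correlated or model-misspecified noise, which is
exactly the situation in which signature-level meta-analysis inherits the
assumptions of its upstream DE models.

A documented calibration run (20 seeds at `noise_sd = 0.1`) put the k ≥ 3
convergent-report sensitivity for planted genes at mean 0.88 (minimum
0.82) with zero false-discovery proportion; the recovery tests assert the
frozen 0.8/0.1 bounds. The residual sensitivity gap is structural: a
Normal(0, 2) program effect lies below the detectability implied by the
1.25-fold threshold for roughly one gene in seven, and such genes are
invisible to any threshold-based pipeline.

## Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; the pipeline fans one
configuration seed out deterministically per context, and all outputs are
plain text written deterministically, so a rerun under one seed reproduces
the output tree byte for byte. The test suite exercises full runs at the
default 28-context, 1000-gene collection, 20-seed stability loops for the
sign structure and convergence recovery, and 50-seed loops for clock shift
detection — sizes chosen so the planted effects dominate sampling error in
the fractions being asserted while the whole suite stays interactive.

## Known limitations

* The pipeline consumes DEG tables; it cannot correct errors or covariate
  confounding inherited from upstream DE analyses (the emulated design
  controlled for sex there).
* ORA is a stand-in for richer enrichment frameworks: no term clustering,
  ontology merging, or redundancy control across sets.
* The exact-permutation Spearman path enumerates n! permutations and is
  only engaged for n ≤ 10.
* `fdr >= pvalue` is asserted only for internally computed adjustments;
  externally supplied fdr columns are accepted as published, even when
  inconsistent with their raw p-values.
* The clock applier assumes the coefficient file's transform matches the
  training transform of the clock it encodes; it cannot validate that
  claim.
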