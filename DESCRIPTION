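Package: gerosig
Title: Cross-Cohort Meta-Analysis of Geroprotective Transcriptomic Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing differential gene-expression signatures of
    geroprotective interventions (senolysis, caloric restriction, partial
    reprogramming, heterochronic parabiosis) with aging and chronic-inflammation
    signatures across studies, organs and cell types. Implements DEG selection at
    fold-change/FDR thresholds, pairwise Spearman correlation of shared-DEG fold
    changes, trend-aware intersection of direction-specific DEG sets,
    hypergeometric gene-set over-representation with weighted pathway rank
    scores, signed consistency score maps, single-cell ambient-RNA DEG hygiene
    filters, and application of linear transcriptomic aging clocks with
    cross-species homolog mapping. A synthetic-data generator plants a signed
    aging program, enriched gene sets, marker/contaminant fixtures and a linear
    clock so that every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
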