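# Hypergeometric over-representation and weighted pathway rank scores.
#
# ORA follows the stated list-analysis parameters (min overlap 2, p < 0.01,
# enrichment >= 1.5); significant pathway hits are then aggregated across
# contexts into a weighted rank score (whole-organ hit = 1 point,
# parabiosis cell-type hit = 0.5 points, FDR < 0.01), and for the
# chronic-inflammation models into signed +1/-1 score maps split by
# modality.

#' Hypergeometric over-representation test of a gene list
#'
#' Upper-tail hypergeometric p-value of the overlap between `deg_list` and
#' each set in `library`, against the library background. List genes
#' outside the background are dropped (count recorded in the
#' `"n_dropped"` attribute). BH FDR is computed across all tested sets
#' before filtering; reported rows must satisfy all three filters:
#' `overlap >= min_overlap`, `pvalue < p_cutoff` and
#' `fold_enrichment >= min_enrichment`.
#'
#' @param deg_list Character vector of genes.
#' @param library A [gene_set_library()].
#' @param min_overlap Minimum overlap (default 2).
#' @param p_cutoff Raw p-value cutoff, strict (default 0.01).
#' @param min_enrichment Minimum fold enrichment (default 1.5).
#' @return Data.frame of class `"enrichment_result"`: `set_id`, `overlap`,
#'   `list_size`, `set_size`, `background_size`, `fold_enrichment`,
#'   `pvalue`, `fdr`.
#' @export
ora_test <- function(deg_list, library, min_overlap = 2, p_cutoff = 0.01,
                     min_enrichment = 1.5) {
  stopifnot(inherits(library, "gene_set_library"))
  bg <- library$background
  if (!length(bg)) stopf("empty background")
  deg_list <- unique(as.character(deg_list))
  kept <- deg_list[deg_list %in% bg]
  n_dropped <- length(deg_list) - length(kept)
  N <- length(bg)
  n <- length(kept)
  empty <- data.frame(set_id = character(0), overlap = integer(0),
                      list_size = integer(0), set_size = integer(0),
                      background_size = integer(0),
                      fold_enrichment = numeric(0), pvalue = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "n_dropped") <- n_dropped
    class(empty) <- c("enrichment_result", "data.frame")
    return(empty)
  }
  ids <- names(library$sets)
  K <- lengths(library$sets)
  k <- vapply(library$sets, function(s) sum(kept %in% s), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fdr <- bh_adjust(p)
  fe <- (k / n) / (K / N)
  res <- data.frame(set_id = ids, overlap = as.integer(k),
                    list_size = n, set_size = as.integer(K),
                    background_size = N, fold_enrichment = fe,
                    pvalue = p, fdr = fdr, stringsAsFactors = FALSE)
  res <- res[res$overlap >= min_overlap & res$pvalue < p_cutoff &
               res$fold_enrichment >= min_enrichment, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- n_dropped
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Weighted pathway rank scores across contexts
#'
#' Aggregates enrichment hits over contexts: each whole-organ (bulk) hit
#' with `fdr < fdr_cutoff` contributes `weights["bulk"]` points (default 1)
#' and each cell-type-resolved (single-cell, i.e. parabiosis-derived) hit
#' contributes `weights["single_cell"]` points (default 0.5).
#'
#' @param results Data.frame of enrichment rows across contexts; must have
#'   columns `set_id`, `fdr`, `modality`.
#' @param fdr_cutoff Strict FDR cutoff for a hit (default 0.01).
#' @param weights Named numeric, points per hit by modality.
#' @param items Optional complete item universe (e.g. every tested set);
#'   items without hits are reported with score 0 so score tables from the
#'   same library are comparable. Default: only items with hits.
#' @return Data.frame `item`, `score`, `n_hits`, sorted by descending
#'   score.
#' @export
pathway_rank_scores <- function(results, fdr_cutoff = 0.01,
                                weights = c(bulk = 1, single_cell = 0.5),
                                items = NULL) {
  stopifnot(all(c("set_id", "fdr", "modality") %in% names(results)))
  bad <- setdiff(unique(results$modality), names(weights))
  if (length(bad)) stopf("no weight for modality '%s'", bad[1L])
  hits <- results[results$fdr < fdr_cutoff, , drop = FALSE]
  if (nrow(hits)) {
    w <- weights[hits$modality]
    score <- tapply(w, hits$set_id, sum)
    n_hits <- tapply(w, hits$set_id, length)
    out <- data.frame(item = names(score), score = as.numeric(score),
                      n_hits = as.integer(n_hits), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(item = character(0), score = numeric(0),
                      n_hits = integer(0), stringsAsFactors = FALSE)
  }
  if (!is.null(items)) {
    zero <- setdiff(items, out$item)
    if (length(zero))
      out <- rbind(out, data.frame(item = zero, score = 0, n_hits = 0L,
                                   stringsAsFactors = FALSE))
  }
  out <- out[order(-out$score, out$item), ]
  rownames(out) <- NULL
  out
}

#' Spearman correlation between two rank-score tables
#'
#' Joins the two tables on the union of items (an item absent from one
#' table scores 0 there) and rank-correlates the scores, reusing the
#' Spearman machinery of the correlation stage. Requires at least 3 items
#' in the union.
#'
#' @param scores_a,scores_b Data.frames with `item` and a score column
#'   (`score`, or `bulk_score`/`sc_score` selected via `column`).
#' @param column Score column name (default `"score"`).
#' @return List with `rho`, `pvalue`, `n`.
#' @export
rank_score_correlation <- function(scores_a, scores_b, column = "score") {
  for (s in list(scores_a, scores_b))
    stopifnot(all(c("item", column) %in% names(s)))
  items <- sort(union(scores_a$item, scores_b$item))
  if (length(items) < 3L) stopf("need >= 3 items to correlate rank scores")
  a <- scores_a[[column]][match(items, scores_a$item)]
  b <- scores_b[[column]][match(items, scores_b$item)]
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  spearman_stat(a, b)
}

#' Signed chronic-inflammation gene score map
#'
#' For each gene, the signed number of chronic-inflammation contexts where
#' it is a DEG, split by modality: upregulation scores +1, downregulation
#' scores -1, summed over bulk organs (`bulk_score`) and over single-cell
#' cell types (`sc_score`). Scores are integers bounded by the number of
#' contexts per modality.
#'
#' @param tables List of `signature_table`s from chronic-inflammation
#'   models (each with a context).
#' @param thr A [deg_thresholds()].
#' @return Data.frame `gene`, `bulk_score`, `sc_score` covering every gene
#'   that is a DEG in at least one table; genes never a DEG are absent
#'   (implicitly (0, 0)).
#' @export
ci_gene_scores <- function(tables, thr = deg_thresholds()) {
  rows <- lapply(tables, function(t) {
    ctx <- sig_context(t)
    if (is.null(ctx)) stopf("every table must carry a context_key")
    d <- select_degs(t, thr, "both")
    if (nrow(d) == 0L) return(NULL)
    data.frame(gene = d$gene,
               sign = ifelse(d$direction == "up", 1L, -1L),
               modality = ctx$modality, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(gene = character(0), bulk_score = integer(0),
                      sc_score = integer(0), stringsAsFactors = FALSE))
  genes <- sort(unique(rows$gene))
  agg <- function(mod) {
    sub <- rows[rows$modality == mod, , drop = FALSE]
    s <- tapply(sub$sign, sub$gene, sum)
    out <- integer(length(genes))
    out[match(names(s), genes)] <- as.integer(s)
    out
  }
  data.frame(gene = genes, bulk_score = agg("bulk"),
             sc_score = agg("single_cell"), stringsAsFactors = FALSE)
}

#' Signed chronic-inflammation pathway score map
#'
#' Like [ci_gene_scores()] but at pathway level: enrichment is computed
#' separately on the up- and down-regulated DEG lists of every
#' chronic-inflammation context, and each enriched context
#' (`fdr < fdr_cutoff`) contributes +1 (up-list) or -1 (down-list) to the
#' set's score in its modality.
#'
#' @param results Data.frame of enrichment rows with columns `set_id`,
#'   `fdr`, `modality`, `direction` (`"up"`/`"down"` of the tested DEG
#'   list).
#' @param fdr_cutoff Strict FDR cutoff for a hit (default 0.01).
#' @return Data.frame `item`, `bulk_score`, `sc_score`.
#' @export
ci_pathway_scores <- function(results, fdr_cutoff = 0.01) {
  stopifnot(all(c("set_id", "fdr", "modality", "direction") %in% names(results)))
  hits <- results[results$fdr < fdr_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(item = character(0), bulk_score = integer(0),
                      sc_score = integer(0), stringsAsFactors = FALSE))
  hits$sign <- ifelse(hits$direction == "up", 1L, -1L)
  items <- sort(unique(hits$set_id))
  agg <- function(mod) {
    sub <- hits[hits$modality == mod, , drop = FALSE]
    s <- tapply(sub$sign, sub$set_id, sum)
    out <- integer(length(items))
    out[match(names(s), items)] <- as.integer(s)
    out
  }
  data.frame(item = items, bulk_score = agg("bulk"),
             sc_score = agg("single_cell"), stringsAsFactors = FALSE)
}

#' Overlay highlighted items on a score table
#'
#' Joins trend labels (e.g. the convergent GI genes or pathways) onto a
#' score map; highlighted items absent from the score table are reported
#' with zero scores so the overlay is complete.
#'
#' @param scores Score data.frame with an item column (`item` or `gene`)
#'   and numeric score column(s).
#' @param highlight Data.frame with the same item column and a `trend`
#'   column.
#' @return The score table with `highlight` (logical) and `trend`
#'   (character or NA) columns appended, plus zero-score rows for
#'   highlighted items missing from `scores`.
#' @export
overlay_report <- function(scores, highlight) {
  item_col <- if ("item" %in% names(scores)) "item" else "gene"
  stopifnot(item_col %in% names(scores))
  out <- scores
  if (nrow(highlight) && !all(c(item_col, "trend") %in% names(highlight)))
    stopf("highlight must have columns '%s' and 'trend'", item_col)
  missing_items <- setdiff(highlight[[item_col]], scores[[item_col]])
  if (length(missing_items)) {
    add <- out[0, , drop = FALSE][seq_along(missing_items), , drop = FALSE]
    add[[item_col]] <- missing_items
    num <- vapply(out, is.numeric, logical(1))
    for (cn in names(out)[num]) add[[cn]] <- 0
    out <- rbind(out, add)
  }
  m <- match(out[[item_col]], highlight[[item_col]])
  out$highlight <- !is.na(m)
  out$trend <- ifelse(is.na(m), NA_character_, highlight$trend[m])
  rownames(out) <- NULL
  out
}
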