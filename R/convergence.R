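# Trend-aware convergence of direction-specific DEG sets.
#
# Each intervention contributes an up- and a down-regulated DEG set built
# with its own context-count rule (a gene must be a DEG, in the matching
# direction, in at least `min_contexts` distinct organs/cell types). The
# two opposing trends are then intersected: genes up in GIs are matched
# against genes down in the young parabiont and down in the global aging
# list, and vice versa. Genes shared by >= k of the six sets form the
# convergent signature.

#' Context-count rule for an intervention DEG set
#'
#' The defaults mirror the study design: 1 organ suffices for senolysis,
#' 2 organs for caloric restriction and reprogramming, 3 cell types for
#' heterochronic parabiosis (the same >= 3 rule applies to the young
#' parabiont).
#'
#' @param intervention Intervention label.
#' @param min_contexts Minimum number of distinct units (organs/cell types)
#'   in which the gene must be a direction-matching DEG.
#' @param direction `"up"` or `"down"`.
#' @return Object of class `"intervention_rule"`.
#' @export
intervention_rule <- function(intervention, min_contexts,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  min_contexts <- check_count(min_contexts, "min_contexts", min = 1L)
  stopifnot(is.character(intervention), nzchar(intervention))
  structure(list(intervention = intervention, min_contexts = min_contexts,
                 direction = direction),
            class = "intervention_rule")
}

#' Direction-specific DEG set of one intervention
#'
#' A gene is included iff it is a DEG in the rule's direction in at least
#' `min_contexts` distinct units among the intervention's tables. A gene up
#' in one organ and down in another counts toward each direction's tally
#' separately; there is no cancellation.
#'
#' @param tables List of `signature_table`s, all from the rule's
#'   intervention.
#' @param rule An [intervention_rule()].
#' @param thr A [deg_thresholds()].
#' @return Character vector of gene symbols.
#' @export
intervention_deg_set <- function(tables, rule, thr = deg_thresholds()) {
  stopifnot(inherits(rule, "intervention_rule"))
  ctxs <- lapply(tables, sig_context)
  ivs <- vapply(ctxs, function(c) c$intervention %||% "", character(1))
  if (any(ivs != rule$intervention))
    stopf("table intervention '%s' does not match rule '%s'",
          ivs[ivs != rule$intervention][1L], rule$intervention)
  units <- vapply(ctxs, function(c) c$unit, character(1))
  hits <- lapply(seq_along(tables), function(i) {
    g <- select_degs(tables[[i]], thr, rule$direction)$gene
    if (!length(g)) return(NULL)
    unique(data.frame(gene = g, unit = units[i], stringsAsFactors = FALSE))
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) return(character(0))
  counts <- table(unique(hits)$gene)
  sort(names(counts)[counts >= rule$min_contexts])
}

trend_set_names <- function(gi_sets) c(names(gi_sets), "ypar", "aging")

#' Intersect one trend's six DEG sets
#'
#' A trend combines direction-matched sets: `"gi_down"` pairs the four GI
#' down-sets with the young-parabiont up-set and the upregulated global
#' aging genes (GIs reverse what aging raises); `"gi_up"` is the mirror
#' image. Each gene occurring in at least one set gets a membership vector
#' over the six sets.
#'
#' @param gi_sets Named list of four GI gene sets (already built in the
#'   trend's GI direction).
#' @param ypar_set Young-parabiont gene set (built in the opposite
#'   direction to the GI sets).
#' @param aging_list Signed reference data.frame (`gene`, `direction`) of
#'   global aging genes.
#' @param trend `"gi_up"` or `"gi_down"`.
#' @return Data.frame: `gene`, `trend`, one logical column per set,
#'   `n_sets`.
#' @export
trend_intersection <- function(gi_sets, ypar_set, aging_list,
                               trend = c("gi_up", "gi_down")) {
  trend <- match.arg(trend)
  stopifnot(is.list(gi_sets), !is.null(names(gi_sets)))
  aging_dir <- if (trend == "gi_up") "down" else "up"
  aging_set <- aging_list$gene[aging_list$direction == aging_dir]
  sets <- c(gi_sets, list(ypar = ypar_set, aging = aging_set))
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  if (!length(genes)) {
    out <- data.frame(gene = character(0), trend = character(0),
                      stringsAsFactors = FALSE)
    for (nm in names(sets)) out[[nm]] <- logical(0)
    out$n_sets <- integer(0)
    return(out)
  }
  mem <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  mem <- matrix(mem, nrow = length(genes),
                dimnames = list(NULL, names(sets)))
  out <- data.frame(gene = genes, trend = trend, stringsAsFactors = FALSE)
  for (nm in colnames(mem)) out[[nm]] <- mem[, nm]
  out$n_sets <- as.integer(rowSums(mem))
  out[out$n_sets >= 1L, , drop = FALSE]
}

#' Report genes shared by at least k sets, with their fold-change profile
#'
#' Filters trend memberships to `n_sets >= k`, sorts by (trend, descending
#' n_sets, gene) and appends the per-context log2 fold-change matrix (`NA`
#' where a gene was not measured in a context). Genes qualifying for both
#' opposing trends indicate conflicting data; they are flagged in a
#' `conflict` column, never silently merged or dropped.
#'
#' @param memberships Data.frame from [trend_intersection()], possibly
#'   row-bound over both trends.
#' @param tables Optional list of `signature_table`s used to fill the
#'   fold-change matrix.
#' @param k Minimum number of sets (default 3).
#' @return Data.frame: `gene`, `trend`, `n_sets`, `conflict`, membership
#'   columns, then one `log2fc.<context>` column per table.
#' @export
shared_gene_report <- function(memberships, tables = NULL, k = 3) {
  k <- check_count(k, "k", min = 1L)
  rep <- memberships[memberships$n_sets >= k, , drop = FALSE]
  # a gene present under both trends is a conflict wherever it appears
  conflict_genes <- intersect(
    memberships$gene[memberships$trend == "gi_up"],
    memberships$gene[memberships$trend == "gi_down"])
  rep$conflict <- rep$gene %in% conflict_genes
  rep <- rep[order(rep$trend, -rep$n_sets, rep$gene), , drop = FALSE]
  rownames(rep) <- NULL
  if (!is.null(tables) && nrow(rep)) {
    for (tab in tables) {
      ctx <- sig_context(tab)
      col <- paste0("log2fc.", if (is.null(ctx)) "table" else context_id(ctx))
      rep[[col]] <- tab$log2fc[match(rep$gene, tab$gene)]
    }
  }
  rep
}

#' Venn-region counts of a trend membership table
#'
#' Counts genes per region of the membership Venn diagram (a region is an
#' exact combination of sets). Region counts partition the retained genes.
#'
#' @param memberships Output of [trend_intersection()] for one trend.
#' @return Data.frame `region`, `n_sets`, `count`.
#' @export
venn_region_counts <- function(memberships) {
  set_cols <- setdiff(names(memberships), c("gene", "trend", "n_sets"))
  region <- apply(memberships[, set_cols, drop = FALSE], 1, function(r)
    paste(set_cols[as.logical(r)], collapse = "&"))
  tab <- table(region)
  out <- data.frame(region = names(tab),
                    n_sets = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$n_sets, out$region), ]
}

#' Direction consistency of a gene across contexts
#'
#' Among the contexts where the gene is a DEG, the fraction changing in the
#' majority direction. Always in [0.5, 1]; 1 means perfectly consistent.
#'
#' @param gene Gene symbol.
#' @param tables List of `signature_table`s.
#' @param thr A [deg_thresholds()].
#' @return Fraction in [0.5, 1].
#' @export
direction_consistency <- function(gene, tables, thr = deg_thresholds()) {
  dirs <- unlist(lapply(tables, function(t) {
    d <- select_degs(t, thr, "both")
    d$direction[d$gene == gene]
  }))
  if (!length(dirs)) stopf("gene '%s' is not a DEG in any table", gene)
  max(sum(dirs == "up"), sum(dirs == "down")) / length(dirs)
}
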