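# Single-cell DEG hygiene: expression prefilter and the two-criteria
# ambient-RNA exclusion heuristic.
#
# Droplet libraries carry cell-free "ambient" transcripts that make strong
# markers of abundant cell types appear differentially expressed in other
# cell types. The exclusion rule is deliberately conservative: a DEG of
# cell type c is removed only when it is BOTH a top-ranked marker of some
# other cell type AND among the most highly expressed genes of the whole
# dataset.

#' Marker table
#'
#' Ranked marker genes per cell type (rank 1 = strongest) with their
#' ranking statistic. The ranking method is injectable: any upstream marker
#' caller may supply the table.
#'
#' @param df Data.frame with columns `cell_type`, `gene`, `rank`,
#'   `statistic`.
#' @return Data.frame of class `"marker_table"`.
#' @export
marker_table <- function(df) {
  need <- c("cell_type", "gene", "rank", "statistic")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("marker table lacks columns: %s",
                          paste(miss, collapse = ", "))
  dup <- unlist(lapply(split(df$rank, df$cell_type), function(r)
    anyDuplicated(r) > 0))
  if (any(dup))
    stopf("duplicated marker rank within cell type '%s'", names(dup)[dup][1L])
  df <- df[, need]
  df$gene <- as.character(df$gene)
  df$cell_type <- as.character(df$cell_type)
  class(df) <- c("marker_table", "data.frame")
  df
}

#' @rdname marker_table
#' @param path Tab-separated file with the marker-table columns.
#' @export
read_marker_table <- function(path) marker_table(read_tsv(path))

#' Expression prefilter for single-cell DEG testing
#'
#' Keeps genes expressed in more than `min_frac` of cells and detected
#' above `min_umi` UMIs in more than `min_cells` cells (both strict, the
#' stated prefilter for per-cell-type DEG testing).
#'
#' @param counts Gene x cell count matrix (dense or `Matrix` sparse),
#'   nonnegative integers, with gene rownames.
#' @param min_frac Minimum detected-cell fraction, strict (default 0.01).
#' @param min_cells Minimum number of cells above `min_umi`, strict
#'   (default 5).
#' @param min_umi UMI bound, strict (default 1).
#' @return Character vector of retained genes.
#' @export
prefilter_genes <- function(counts, min_frac = 0.01, min_cells = 5,
                            min_umi = 1) {
  if (is.null(dim(counts)) || ncol(counts) == 0L)
    stopf("counts must have >= 1 cell")
  if (is.null(rownames(counts))) stopf("counts must have gene rownames")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  detected <- Matrix::rowSums(counts > 0)
  deep <- Matrix::rowSums(counts > min_umi)
  keep <- (detected / ncol(counts) > min_frac) & (deep > min_cells)
  rownames(counts)[keep]
}

#' Dataset-wide expression ranking
#'
#' Ranks genes by total expression summed over all cells, after optional
#' library-size normalization (each cell scaled to unit total, the default,
#' so deeply sequenced cells do not dominate). Ties are broken by gene
#' symbol so the ranking is deterministic.
#'
#' @param counts Gene x cell count matrix with gene rownames.
#' @param normalize Library-size-normalize cells before summing
#'   (default `TRUE`).
#' @return Data.frame `gene`, `total`, `rank` (1 = most highly expressed).
#' @export
rank_expression <- function(counts, normalize = TRUE) {
  if (is.null(rownames(counts))) stopf("counts must have gene rownames")
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (normalize) {
    libsize <- Matrix::colSums(counts)
    libsize[libsize == 0] <- 1
    totals <- as.numeric(counts %*% (1 / libsize))
  } else {
    totals <- Matrix::rowSums(counts)
  }
  names(totals) <- rownames(counts)
  ord <- order(-totals, names(totals))
  data.frame(gene = names(totals)[ord], total = totals[ord],
             rank = seq_along(totals), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-criteria ambient-RNA DEG exclusion
#'
#' A DEG of `cell_type` is excluded iff it is (1) among the top
#' `top_markers` markers of some other cell type AND (2) among the top
#' `top_expressed` most highly expressed genes of the dataset. Rank bounds
#' are inclusive ("among the top 5" includes rank 5). Every exclusion
#' records the offending cell type and both ranks.
#'
#' @param degs Character vector of DEGs called in `cell_type`.
#' @param cell_type The cell type whose DEGs are filtered.
#' @param markers A [marker_table()] containing `cell_type`.
#' @param expr_ranks Data.frame `gene`, `rank` from [rank_expression()].
#' @param top_markers Marker-rank bound, inclusive (default 5).
#' @param top_expressed Expression-rank bound, inclusive (default 50).
#' @return List with `retained` (character) and `excluded` (data.frame
#'   `gene`, `offending_cell_type`, `marker_rank`, `expression_rank`).
#' @export
filter_ambient_degs <- function(degs, cell_type, markers, expr_ranks,
                                top_markers = 5, top_expressed = 50) {
  stopifnot(inherits(markers, "marker_table"))
  if (!cell_type %in% markers$cell_type)
    stopf("cell type '%s' absent from marker table", cell_type)
  top <- markers[markers$rank <= top_markers &
                   markers$cell_type != cell_type, , drop = FALSE]
  er <- expr_ranks$rank[match(degs, expr_ranks$gene)]
  m <- match(degs, top$gene)
  is_foreign_marker <- !is.na(m)
  is_highly_expressed <- !is.na(er) & er <= top_expressed
  out <- is_foreign_marker & is_highly_expressed
  excluded <- data.frame(
    gene = degs[out],
    offending_cell_type = top$cell_type[m[out]],
    marker_rank = top$rank[m[out]],
    expression_rank = er[out],
    stringsAsFactors = FALSE)
  list(retained = degs[!out], excluded = excluded)
}

#' Read a count matrix (dense delimited or MatrixMarket)
#'
#' Dense: tab-separated with gene rownames in the first column and sample
#' headers. MTX: `path` plus sidecar files holding row (gene) and column
#' names, one per line.
#'
#' @param path Count file.
#' @param format `"auto"` (by extension), `"dense"` or `"mtx"`.
#' @param genes_file,cells_file Sidecar name files for MTX input; default
#'   `<path>.genes` / `<path>.cells`.
#' @return A base dense matrix (dense input) or `Matrix` sparse matrix
#'   (MTX input), genes x cells.
#' @export
read_counts <- function(path, format = c("auto", "dense", "mtx"),
                        genes_file = NULL, cells_file = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "dense") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE)
    return(as.matrix(df))
  }
  m <- Matrix::readMM(path)
  genes_file <- genes_file %||% paste0(path, ".genes")
  cells_file <- cells_file %||% paste0(path, ".cells")
  rownames(m) <- readLines(genes_file, warn = FALSE)
  colnames(m) <- readLines(cells_file, warn = FALSE)
  m
}
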