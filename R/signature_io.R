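#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment. Values are validated to lie in
#' [0, 1]; the output preserves input order, is monotone-enforced and capped
#' at 1.
#'
#' @param pvalues Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stopf("p-values must be numeric")
  if (anyNA(pvalues)) stopf("p-values must not contain NA")
  if (any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Construct a signature table
#'
#' One context's per-gene differential-expression statistics: gene symbol,
#' log2 fold-change, raw p-value and BH-adjusted p-value (`fdr`). If `fdr`
#' is omitted it is computed from `pvalue` with [bh_adjust()]. Externally
#' supplied `fdr` columns are accepted as-is (original-study DEG calls are
#' adopted, not recomputed).
#'
#' @param gene Character vector of unique gene symbols.
#' @param log2fc Finite numeric log2 fold-changes.
#' @param pvalue Raw p-values in [0, 1].
#' @param fdr Optional adjusted p-values in [0, 1].
#' @param context Optional [context_key()] attached as an attribute.
#' @return A data.frame of class `"signature_table"` with columns
#'   `gene`, `log2fc`, `pvalue`, `fdr`.
#' @export
signature_table <- function(gene, log2fc, pvalue, fdr = NULL, context = NULL) {
  if (!is.character(gene)) gene <- as.character(gene)
  n <- length(gene)
  if (length(log2fc) != n || length(pvalue) != n)
    stopf("gene, log2fc and pvalue must have equal length")
  dup <- gene[duplicated(gene)]
  if (length(dup))
    stopf("duplicate gene symbol in signature table: %s", dup[1L])
  if (!is.numeric(log2fc) || anyNA(log2fc) || any(!is.finite(log2fc)))
    stopf("log2fc must be finite numeric")
  if (!is.numeric(pvalue) || anyNA(pvalue) || any(pvalue < 0 | pvalue > 1))
    stopf("pvalue must be numeric in [0, 1]")
  internal_fdr <- is.null(fdr)
  if (internal_fdr) {
    fdr <- bh_adjust(pvalue)
  } else {
    if (length(fdr) != n) stopf("fdr must match table length")
    if (!is.numeric(fdr) || anyNA(fdr) || any(fdr < 0 | fdr > 1))
      stopf("fdr must be numeric in [0, 1]")
  }
  if (internal_fdr && any(fdr < pvalue - 1e-12))
    stopf("internal BH adjustment produced fdr below raw p") # never expected
  out <- data.frame(gene = gene, log2fc = as.numeric(log2fc),
                    pvalue = as.numeric(pvalue), fdr = as.numeric(fdr),
                    stringsAsFactors = FALSE)
  class(out) <- c("signature_table", "data.frame")
  if (!is.null(context)) {
    stopifnot(inherits(context, "context_key"))
    attr(out, "context") <- context
  }
  out
}

#' Context attached to a signature table
#' @param table A `signature_table`.
#' @return The [context_key()] or `NULL`.
#' @export
sig_context <- function(table) attr(table, "context")

#' Read a signature table from a delimited file
#'
#' Expects a tab-separated file with header columns `gene`, `log2fc`,
#' `pvalue` and optionally `fdr`; a missing `fdr` column is filled by BH
#' adjustment of `pvalue`. With `fc_scale = "linear"` the fold-change column
#' may be named `fc` and is converted to log2 at read time (DESeq2/MAST
#' convention is log2, so that is the default dialect).
#'
#' @param path File path.
#' @param context Optional [context_key()] to attach.
#' @param fc_scale `"log2"` (default) or `"linear"`.
#' @param normalize_case Uppercase gene symbols on read (for cross-species
#'   work where symbol casing differs systematically). Default `FALSE`:
#'   symbols are case-sensitive.
#' @return A `signature_table`.
#' @export
read_signature_table <- function(path, context = NULL,
                                 fc_scale = c("log2", "linear"),
                                 normalize_case = FALSE) {
  fc_scale <- match.arg(fc_scale)
  df <- read_tsv(path)
  fc_col <- if (fc_scale == "linear" && "fc" %in% names(df)) "fc" else "log2fc"
  need <- c("gene", fc_col, "pvalue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  for (col in c(fc_col, "pvalue", if ("fdr" %in% names(df)) "fdr")) {
    if (!is.numeric(df[[col]]))
      stopf("%s: column '%s' is not numeric", path, col)
  }
  fc <- df[[fc_col]]
  if (fc_scale == "linear") {
    if (any(fc <= 0)) stopf("%s: linear fold-changes must be positive", path)
    fc <- log2(fc)
  }
  gene <- as.character(df$gene)
  if (normalize_case) gene <- toupper(gene)
  signature_table(gene, fc, df$pvalue,
                  fdr = if ("fdr" %in% names(df)) df$fdr else NULL,
                  context = context)
}

#' @rdname read_signature_table
#' @param table A `signature_table` to write.
#' @export
write_signature_table <- function(table, path) {
  stopifnot(inherits(table, "signature_table"))
  write_tsv(as.data.frame(table)[, c("gene", "log2fc", "pvalue", "fdr")], path)
}

#' DEG selection thresholds
#'
#' Defaults are the meta-analysis thresholds: linear |fold-change| > 1.25
#' and BH-adjusted p < 0.05, both strict inequalities (a fold-change of
#' exactly 1.25 does not qualify).
#'
#' @param min_abs_fc Linear fold-change bound, must exceed 1.
#' @param max_fdr Adjusted-p bound in (0, 1).
#' @return An object of class `"deg_thresholds"`.
#' @export
deg_thresholds <- function(min_abs_fc = 1.25, max_fdr = 0.05) {
  check_number(min_abs_fc, "min_abs_fc", lower = 1, strict_lower = TRUE)
  check_number(max_fdr, "max_fdr", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(min_abs_fc = min_abs_fc, max_fdr = max_fdr),
            class = "deg_thresholds")
}

#' Select differentially expressed genes
#'
#' A gene is selected iff `2^|log2fc| > min_abs_fc` and `fdr < max_fdr`
#' (both strict) and its sign matches `direction`.
#'
#' @param table A `signature_table`.
#' @param thr A [deg_thresholds()].
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Data.frame with columns `gene`, `log2fc`, `direction`.
#' @examples
#' tab <- signature_table(c("A", "B"), c(log2(1.30), log2(1.25)),
#'                        c(0.001, 0.001), fdr = c(0.04, 0.001))
#' select_degs(tab)$gene  # only "A": 1.25 exactly is below the strict bound
#' @export
select_degs <- function(table, thr = deg_thresholds(),
                        direction = c("both", "up", "down")) {
  stopifnot(inherits(table, "signature_table"), inherits(thr, "deg_thresholds"))
  direction <- match.arg(direction)
  keep <- (2^abs(table$log2fc) > thr$min_abs_fc) & (table$fdr < thr$max_fdr)
  if (direction == "up") keep <- keep & table$log2fc > 0
  if (direction == "down") keep <- keep & table$log2fc < 0
  out <- data.frame(gene = table$gene[keep],
                    log2fc = table$log2fc[keep],
                    direction = ifelse(table$log2fc[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene-set library
#'
#' Named gene sets plus the background gene universe used for
#' over-representation tests. Every member must belong to the background.
#'
#' @param sets Named list of character vectors (set id -> member symbols).
#' @param background Character vector, the gene universe.
#' @return Object of class `"gene_set_library"`.
#' @export
gene_set_library <- function(sets, background) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stopf("duplicate set id: %s", names(sets)[duplicated(names(sets))][1L])
  background <- unique(as.character(background))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  out_of_bg <- vapply(sets, function(g) any(!g %in% background), logical(1))
  if (any(out_of_bg))
    stopf("set '%s' has members outside the background",
          names(sets)[out_of_bg][1L])
  if (any(lengths(sets) == 0L)) stopf("empty gene set not allowed")
  structure(list(sets = sets, background = background),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("<gene_set_library> %d sets, background of %d genes\n",
              length(x$sets), length(x$background)))
  invisible(x)
}

#' Read/write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `set_id<TAB>description<TAB>genes...`.
#' Members are deduplicated. The background defaults to the union of all
#' members; supply `background` to use a wider measured universe.
#'
#' @param path GMT file.
#' @param background Optional gene universe (character vector).
#' @return A [gene_set_library()].
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("%s line %d: GMT lines need id, description and >=1 gene",
            path, i)
    sets[[f[1L]]] <- unique(f[-(1:2)])
  }
  gene_set_library(sets, background %||% unique(unlist(sets, use.names = FALSE)))
}

#' @rdname read_gmt
#' @param library A `gene_set_library`.
#' @param descriptions Optional named descriptions per set.
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  ids <- names(library$sets)
  desc <- descriptions[ids] %||% rep("na", length(ids))
  desc[is.na(desc)] <- "na"
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], desc[i], library$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a signed gene reference list
#'
#' Tab-separated file with header `gene`, `direction` and direction values
#' `up`/`down` — the format used for published "global aging gene" lists
#' (genes consistently up- or down-regulated with age across tissues).
#'
#' @param path File path.
#' @return A data.frame with columns `gene`, `direction`.
#' @export
read_gene_list <- function(path) {
  df <- read_tsv(path)
  miss <- setdiff(c("gene", "direction"), names(df))
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$direction), c("up", "down"))
  if (length(bad)) stopf("%s: direction must be 'up'/'down', found '%s'",
                         path, bad[1L])
  df$gene <- as.character(df$gene)
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup)) stopf("%s: duplicated gene '%s'", path, dup[1L])
  df[, c("gene", "direction")]
}

#' @rdname read_gene_list
#' @param genes Data.frame with `gene` and `direction` columns.
#' @export
write_gene_list <- function(genes, path) {
  stopifnot(all(c("gene", "direction") %in% names(genes)))
  write_tsv(genes[, c("gene", "direction")], path)
}
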