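# Pairwise Spearman correlation of fold-changes over shared DEGs.
#
# The correlation stage asks whether two contrasts move the same genes in
# the same (or opposite) direction: each pair of contexts is reduced to the
# genes that are DEGs in BOTH, and the log2 fold-changes of those shared
# DEGs are rank-correlated. Pairs sharing fewer than `min_shared` DEGs are
# excluded (coefficient withheld, shared count retained for audit), and a
# presentation mask records which coefficients reach p < alpha.

#' Shared DEGs of two signature tables
#'
#' Genes that pass [select_degs()] (any direction) in both tables.
#'
#' @param a,b `signature_table`s.
#' @param thr A [deg_thresholds()].
#' @return Character vector of shared DEG symbols.
#' @export
shared_degs <- function(a, b, thr = deg_thresholds()) {
  intersect(select_degs(a, thr, "both")$gene, select_degs(b, thr, "both")$gene)
}

# Iteratively build the k! x k matrix of all permutations of 1..k by
# inserting k into every position of the permutations of 1..(k-1).
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 10)
  P <- matrix(1L, 1L, 1L)
  if (n == 1L) return(P)
  for (k in 2L:n) {
    pieces <- vector("list", k)
    for (j in seq_len(k)) {
      left <- if (j > 1L) P[, seq_len(j - 1L), drop = FALSE] else NULL
      right <- if (j <= k - 1L) P[, j:(k - 1L), drop = FALSE] else NULL
      pieces[[j]] <- cbind(left, k, right, deparse.level = 0)
    }
    P <- do.call(rbind, pieces)
  }
  P
}

# Pearson correlation of two equal-length vectors; NA when either is constant.
pearson_r <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  n <- length(x)
  (sum(x * y) - n * mean(x) * mean(y)) / ((n - 1) * sx * sy)
}

# Exact two-sided permutation p-value for Spearman's rho. Works on ranks
# (average ranks under ties); rho is an affine function of sum(xr * yr[perm])
# because permutation leaves the rank multisets unchanged, so the full
# permutation distribution is computed vectorised.
spearman_perm_pvalue <- function(xr, yr, rho_obs) {
  n <- length(xr)
  P <- all_permutations(n)
  perm_y <- matrix(yr[P], nrow(P), n)
  S <- as.vector(perm_y %*% xr)
  sx <- stats::sd(xr); sy <- stats::sd(yr)
  rho_perm <- (S - n * mean(xr) * mean(yr)) / ((n - 1) * sx * sy)
  mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
}

# rho (average-rank ties) plus two-sided p: exact permutation for n <= 10,
# t-approximation t = rho*sqrt((n-2)/(1-rho^2)) above that.
spearman_stat <- function(x, y, exact_max = 10L) {
  n <- length(x)
  if (n < 2L) stopf("need >= 2 paired observations")
  xr <- rank(x); yr <- rank(y)
  rho <- pearson_r(xr, yr)
  if (is.na(rho)) return(list(rho = NA_real_, pvalue = NA_real_, n = n))
  if (n <= exact_max) {
    p <- spearman_perm_pvalue(xr, yr, rho)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, pvalue = p, n = n)
}

#' Spearman correlation of fold-changes for a gene list
#'
#' Rank correlation (average ranks under ties) of `log2fc` between two
#' signature tables over the given genes. Two-sided p-values come from
#' exact permutation enumeration for n <= 10 and from the t-approximation
#' above that. A constant fold-change vector leaves rho undefined
#' (returned as `NA`).
#'
#' @param a,b `signature_table`s.
#' @param genes Character vector of genes present in both tables (>= 2).
#' @return List with `rho`, `pvalue`, `n`.
#' @export
spearman_pair <- function(a, b, genes) {
  stopifnot(inherits(a, "signature_table"), inherits(b, "signature_table"))
  if (length(genes) < 2L) stopf("need >= 2 genes to correlate")
  ia <- match(genes, a$gene); ib <- match(genes, b$gene)
  if (anyNA(ia) || anyNA(ib))
    stopf("gene(s) absent from a table: %s",
          genes[is.na(ia) | is.na(ib)][1L])
  spearman_stat(a$log2fc[ia], b$log2fc[ib])
}

#' All-pairs correlation matrix over shared DEGs
#'
#' Evaluates every unordered pair of contexts (including the diagonal) once.
#' Pairs sharing fewer than `min_shared` DEGs are excluded: their rho and
#' p-value are `NA` but the shared-DEG count is retained so exclusions stay
#' auditable. The `mask` marks coefficients with p < alpha for presentation.
#'
#' @param tables List of `signature_table`s, each carrying a context.
#' @param thr A [deg_thresholds()].
#' @param min_shared Minimum shared-DEG count (default 10; pairs with fewer
#'   are excluded).
#' @param alpha Significance mask level on the raw p-value (default 0.05).
#' @return Object of class `"correlation_matrix"`: list with `ids`,
#'   `contexts`, symmetric matrices `rho`, `pvalue`, `n_shared`, `mask`,
#'   and the parameters used.
#' @export
correlation_matrix <- function(tables, thr = deg_thresholds(),
                               min_shared = 10, alpha = 0.05) {
  if (length(tables) < 2L) stopf("need >= 2 signature tables")
  ctxs <- lapply(tables, sig_context)
  if (any(vapply(ctxs, is.null, logical(1))))
    stopf("every table must carry a context_key")
  ids <- vapply(ctxs, context_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate context: %s", ids[duplicated(ids)][1L])
  k <- length(tables)
  deg_sets <- lapply(tables, function(t) select_degs(t, thr, "both")$gene)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  nsh <- matrix(0L, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in i:k) {
      genes <- intersect(deg_sets[[i]], deg_sets[[j]])
      nsh[i, j] <- nsh[j, i] <- length(genes)
      if (length(genes) >= max(2L, min_shared)) {
        st <- spearman_pair(tables[[i]], tables[[j]], genes)
        rho[i, j] <- rho[j, i] <- st$rho
        p[i, j] <- p[j, i] <- st$pvalue
      }
    }
  }
  mask <- !is.na(p) & p < alpha
  structure(list(ids = ids, contexts = ctxs, rho = rho, pvalue = p,
                 n_shared = nsh, mask = mask,
                 min_shared = min_shared, alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  k <- length(x$ids)
  off <- upper.tri(x$rho)
  cat(sprintf("<correlation_matrix> %d contexts, %d pairs (%d excluded at < %d shared DEGs, %d significant at p < %g)\n",
              k, sum(off), sum(is.na(x$rho[off])), x$min_shared,
              sum(x$mask[off]), x$alpha))
  invisible(x)
}

#' Long-format pair table of a correlation matrix
#'
#' @param x A `correlation_matrix`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data.frame with one row per unordered off-diagonal pair:
#'   `context_a`, `context_b`, `rho`, `pvalue`, `n_shared`, `masked`.
#' @export
as.data.frame.correlation_matrix <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  k <- length(x$ids)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(context_a = x$ids[idx[, 1]], context_b = x$ids[idx[, 2]],
             rho = x$rho[idx], pvalue = x$pvalue[idx],
             n_shared = x$n_shared[idx], masked = x$mask[idx],
             stringsAsFactors = FALSE)
}

#' Summarise a correlation matrix by metadata blocks
#'
#' Aggregates off-diagonal pairs by a context field (typically `role`):
#' mean available rho per block, and among significant (masked) entries the
#' fraction positive/negative. Supports reading the correlation heatmap at
#' block level, e.g. "every significant GI x AGING correlation is negative".
#'
#' @param x A `correlation_matrix`.
#' @param by Context field to block on (default `"role"`).
#' @return Data.frame with columns `block_a`, `block_b`, `n_pairs`,
#'   `n_available`, `mean_rho`, `n_significant`, `frac_positive`,
#'   `frac_negative`.
#' @export
block_summary <- function(x, by = "role") {
  stopifnot(inherits(x, "correlation_matrix"))
  labs <- vapply(x$contexts, function(c) as.character(c[[by]]), character(1))
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  a <- labs[idx[, 1]]; b <- labs[idx[, 2]]
  block <- ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  rho <- x$rho[idx]; masked <- x$mask[idx]
  out <- do.call(rbind, lapply(sort(unique(block)), function(bl) {
    sel <- block == bl
    r <- rho[sel]; m <- masked[sel]
    avail <- !is.na(r)
    sig <- r[m & avail]
    parts <- strsplit(bl, "|", fixed = TRUE)[[1]]
    data.frame(block_a = parts[1], block_b = parts[2],
               n_pairs = sum(sel), n_available = sum(avail),
               mean_rho = if (any(avail)) mean(r[avail]) else NA_real_,
               n_significant = length(sig),
               frac_positive = if (length(sig)) mean(sig > 0) else NA_real_,
               frac_negative = if (length(sig)) mean(sig < 0) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
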