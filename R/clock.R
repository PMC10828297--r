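# Linear transcriptomic clock application with the cross-species protocol:
# homolog mapping -> length/depth normalization (UMI convention: all gene
# lengths forced to 10 kb) -> linear model evaluation -> per-panel scaling
# -> group comparison.

#' Linear transcriptomic clock model
#'
#' Predicted age (human years) = intercept + sum of coefficient x
#' transformed expression. The expression transform is part of the model:
#' length- and depth-normalized abundance (FPKM-style) passed through
#' `log2(x + pseudocount)`. Coefficients are always an input — trained
#' weights are external to this package.
#'
#' @param intercept Years.
#' @param coefficients Named numeric vector (gene symbol -> years per
#'   transformed-expression unit); at least one nonzero.
#' @param pseudocount Transform pseudocount (default 1).
#' @param tissue Tissue label or `"pan-tissue"`.
#' @return Object of class `"clock_model"`.
#' @export
clock_model <- function(intercept, coefficients, pseudocount = 1,
                        tissue = "pan-tissue") {
  check_number(intercept, "intercept")
  if (!is.numeric(coefficients) || is.null(names(coefficients)) ||
      any(!nzchar(names(coefficients))))
    stopf("coefficients must be a named numeric vector")
  if (all(coefficients == 0)) stopf("clock needs >= 1 nonzero coefficient")
  check_number(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  structure(list(intercept = intercept, coefficients = coefficients,
                 transform = list(type = "log2", pseudocount = pseudocount),
                 tissue = tissue),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: intercept %.3g, %d coefficients (log2, pseudocount %g)\n",
              x$tissue, x$intercept, length(x$coefficients),
              x$transform$pseudocount))
  invisible(x)
}

#' Read/write a clock model file
#'
#' Header comment lines (`# intercept:`, `# pseudocount:`, `# tissue:`)
#' followed by a tab-separated `gene`/`coefficient` table.
#'
#' @param path File path.
#' @return A [clock_model()].
#' @export
read_clock_model <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NULL) {
    hit <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1L]))
  }
  intercept <- as.numeric(get("intercept"))
  if (is.na(intercept)) stopf("%s: missing '# intercept:' header", path)
  pseudocount <- as.numeric(get("pseudocount", "1"))
  tissue <- get("tissue", "pan-tissue")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene", "coefficient") %in% names(df)))
    stopf("%s: needs 'gene' and 'coefficient' columns", path)
  coefs <- stats::setNames(as.numeric(df$coefficient), df$gene)
  clock_model(intercept, coefs, pseudocount = pseudocount, tissue = tissue)
}

#' @rdname read_clock_model
#' @param clock A `clock_model`.
#' @export
write_clock_model <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  hdr <- c(sprintf("# intercept: %.17g", clock$intercept),
           sprintf("# pseudocount: %.17g", clock$transform$pseudocount),
           sprintf("# tissue: %s", clock$tissue),
           "gene\tcoefficient")
  body <- sprintf("%s\t%.17g", names(clock$coefficients), clock$coefficients)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Expression matrix container for clock application
#'
#' @param counts Nonnegative genes x samples matrix with dimnames.
#' @param lengths Named per-gene lengths in bases (required for
#'   `units = "counts"`; ignored for UMIs, whose effective length is forced
#'   to 10,000 bases at normalization).
#' @param groups Optional per-sample group labels.
#' @param units `"counts"` or `"UMI"`.
#' @return Object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(counts, lengths = NULL, groups = NULL,
                              units = c("counts", "UMI")) {
  units <- match.arg(units)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) stopf("abundances must be nonnegative")
  if (!is.null(lengths)) {
    lengths <- lengths[rownames(counts)]
    if (anyNA(lengths) || any(lengths <= 0))
      stopf("every gene needs a positive length")
    names(lengths) <- rownames(counts)
  }
  if (!is.null(groups)) {
    if (length(groups) != ncol(counts))
      stopf("groups must have one label per sample")
    groups <- stats::setNames(as.character(groups), colnames(counts))
  }
  structure(list(counts = counts, lengths = lengths, groups = groups,
                 units = units),
            class = "expression_matrix")
}

#' Map expression rows to homolog symbols
#'
#' Renames genes via a source-to-target homolog map (e.g. mouse to human).
#' Unmapped genes are dropped (count in attribute `"n_unmapped"`);
#' one-to-many source genes take the first listed target (count in
#' `"n_one_to_many"`); many-to-one collisions onto a single target symbol
#' are resolved by `collision_policy`: `"sum"` (default, conserves counts),
#' `"max"` (row with the largest total abundance wins) or `"error"`.
#' With policy `"sum"`/`"max"` the target gene length is the maximum of the
#' collided source lengths.
#'
#' @param expr An [expression_matrix()].
#' @param map Data.frame with columns `source`, `target`.
#' @param collision_policy `"sum"`, `"max"` or `"error"`.
#' @return An `expression_matrix` on target symbols.
#' @export
map_homologs <- function(expr, map, collision_policy = c("sum", "max", "error")) {
  collision_policy <- match.arg(collision_policy)
  stopifnot(inherits(expr, "expression_matrix"),
            all(c("source", "target") %in% names(map)))
  if (nrow(map) == 0L) stopf("homolog map is empty")
  if (any(!nzchar(map$source)) || any(!nzchar(map$target)))
    stopf("homolog map contains empty symbols")
  n_one_to_many <- sum(duplicated(map$source))
  map <- map[!duplicated(map$source), , drop = FALSE]  # first target wins
  tgt <- map$target[match(rownames(expr$counts), map$source)]
  n_unmapped <- sum(is.na(tgt))
  keep <- !is.na(tgt)
  counts <- expr$counts[keep, , drop = FALSE]
  tgt <- tgt[keep]
  lengths <- if (!is.null(expr$lengths)) expr$lengths[keep] else NULL
  if (anyDuplicated(tgt)) {
    collided <- unique(tgt[duplicated(tgt)])
    if (collision_policy == "error")
      stopf("homolog collision onto target symbol(s): %s",
            paste(collided, collapse = ", "))
    groups <- split(seq_along(tgt), tgt)
    counts2 <- t(vapply(groups, function(idx) {
      block <- counts[idx, , drop = FALSE]
      if (collision_policy == "sum") colSums(block)
      else block[which.max(rowSums(block)), ]
    }, numeric(ncol(counts))))
    lengths2 <- if (!is.null(lengths))
      vapply(groups, function(idx) max(lengths[idx]), numeric(1)) else NULL
    counts <- counts2
    lengths <- lengths2
  } else {
    rownames(counts) <- tgt
    if (!is.null(lengths)) names(lengths) <- tgt
  }
  out <- expression_matrix(counts, lengths = lengths, groups = expr$groups,
                           units = expr$units)
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_one_to_many") <- n_one_to_many
  out
}

#' Length- and depth-normalize expression for clock evaluation
#'
#' Computes FPKM-style abundance (counts per kilobase of gene length per
#' million total counts) and applies the clock transform
#' `log2(abundance + pseudocount)`. For UMI matrices every gene length is
#' set to 10,000 bases before normalization (UMI counts carry no length
#' bias; the fixed length keeps them on the clock's abundance scale).
#' An all-zero sample maps to the transform of zero throughout.
#'
#' @param expr An [expression_matrix()].
#' @param pseudocount Transform pseudocount (default 1).
#' @return Transformed genes x samples matrix with attribute
#'   `"pseudocount"`.
#' @export
normalize_for_clock <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  counts <- expr$counts
  if (expr$units == "UMI") {
    lengths <- stats::setNames(rep(10000, nrow(counts)), rownames(counts))
  } else {
    if (is.null(expr$lengths))
      stopf("gene lengths required when units = 'counts'")
    lengths <- expr$lengths
  }
  depth <- colSums(counts)
  depth[depth == 0] <- 1  # all-zero sample: abundance stays zero
  fpkm <- sweep(counts / (lengths / 1000), 2, depth / 1e6, "/")
  out <- log2(fpkm + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Evaluate a linear clock on transformed expression
#'
#' Age = intercept + sum over clock genes of coefficient x transformed
#' expression. Clock genes absent from the matrix are imputed at the
#' transform of zero abundance, `log2(pseudocount)` (count in attribute
#' `"n_imputed"`); if no clock gene is present the call errors.
#'
#' @param expr_t Transformed matrix from [normalize_for_clock()].
#' @param clock A [clock_model()].
#' @return Named numeric vector of per-sample ages (years).
#' @export
apply_clock <- function(expr_t, clock) {
  stopifnot(inherits(clock, "clock_model"))
  coefs <- clock$coefficients
  present <- intersect(names(coefs), rownames(expr_t))
  if (!length(present)) stopf("no clock gene present in the expression matrix")
  missing <- setdiff(names(coefs), present)
  t0 <- log2(clock$transform$pseudocount)
  ages <- clock$intercept +
    as.vector(t(expr_t[present, , drop = FALSE]) %*% coefs[present]) +
    sum(coefs[missing]) * t0
  out <- stats::setNames(ages, colnames(expr_t))
  attr(out, "n_imputed") <- length(missing)
  out
}

#' Scale clock readouts within presentation panels
#'
#' @param ages Named numeric vector of ages (years).
#' @param method `"none"`, `"zscore"` (population standard deviation, so
#'   two samples scale to -1/+1) or `"minmax"`.
#' @param panels Optional per-sample panel labels; scaling is applied
#'   within each panel (default: one panel).
#' @return Numeric vector of scaled readouts with attribute `"method"`.
#' @export
scale_ages <- function(ages, method = c("none", "zscore", "minmax"),
                       panels = NULL) {
  method <- match.arg(method)
  panels <- panels %||% rep("all", length(ages))
  if (length(panels) != length(ages)) stopf("one panel label per sample")
  out <- ages
  for (p in unique(panels)) {
    idx <- panels == p
    x <- ages[idx]
    if (method == "none") next
    if (length(x) < 2L) stopf("panel '%s' needs >= 2 samples to scale", p)
    if (method == "zscore") {
      s <- sqrt(mean((x - mean(x))^2))
      if (s == 0) {
        warning(sprintf("panel '%s': constant ages, zscore set to 0", p))
        out[idx] <- 0
      } else out[idx] <- (x - mean(x)) / s
    } else {
      r <- range(x)
      if (diff(r) == 0) {
        warning(sprintf("panel '%s': constant ages, minmax set to 0", p))
        out[idx] <- 0
      } else out[idx] <- (x - r[1]) / diff(r)
    }
  }
  attr(out, "method") <- method
  out
}

#' Compare clock ages between two groups
#'
#' Difference of group means (second level minus first) and a two-sided
#' rank-sum p-value, exact (full enumeration) when sample sizes are small
#' and there are no ties, normal approximation otherwise.
#'
#' @param ages Numeric vector of ages.
#' @param groups Vector with exactly two distinct labels; factor level
#'   order (or sort order) defines the direction of `delta`.
#' @return List with `delta`, `pvalue`, `groups`, `n`.
#' @export
compare_groups <- function(ages, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("need exactly two groups")
  x <- ages[groups == levels(groups)[1L]]
  y <- ages[groups == levels(groups)[2L]]
  if (length(x) < 2L || length(y) < 2L)
    stopf("each group needs >= 2 samples")
  ties <- anyDuplicated(c(x, y)) > 0
  wt <- suppressWarnings(stats::wilcox.test(
    y, x, exact = !ties && length(x) + length(y) <= 50, correct = TRUE))
  list(delta = mean(y) - mean(x), pvalue = wt$p.value,
       groups = levels(groups), n = c(length(x), length(y)))
}

#' Read/write per-gene lengths and per-sample groups
#'
#' Helpers for the clock protocol's sidecar files: `gene`/`length` and
#' `sample`/`group`/`panel` tab-separated tables.
#'
#' @param path File path.
#' @return `read_gene_lengths()`: named numeric vector;
#'   `read_sample_groups()`: data.frame `sample`, `group`, `panel`.
#' @export
read_gene_lengths <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("gene", "length") %in% names(df)))
  stats::setNames(as.numeric(df$length), df$gene)
}

#' @rdname read_gene_lengths
#' @export
read_sample_groups <- function(path) {
  df <- read_tsv(path)
  miss <- setdiff(c("sample", "group"), names(df))
  if (length(miss)) stopf("%s: missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  if (is.null(df$panel)) df$panel <- "all"
  df[, c("sample", "group", "panel")]
}
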