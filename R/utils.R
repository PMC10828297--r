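# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# Keeps every stochastic operation reproducible without clobbering the
# session RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  if (strict_lower && x <= lower) stopf("'%s' must exceed %s", name, lower)
  if (!strict_lower && x < lower) stopf("'%s' must be >= %s", name, lower)
  if (strict_upper && x >= upper) stopf("'%s' must be below %s", name, upper)
  if (!strict_upper && x > upper) stopf("'%s' must be <= %s", name, upper)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
    stopf("'%s' must be a single integer", name)
  if (x < min) stopf("'%s' must be >= %d", name, min)
  as.integer(x)
}

# deterministic TSV writer used for every tabular output
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
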