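#' Context metadata for a differential-expression signature
#'
#' A context addresses one differential-expression contrast: the study it
#' came from, the comparison (group), the organ or cell type it was measured
#' in, whether it is bulk or single-cell, and its role in the meta-analysis.
#' Roles follow the study design: `GI` for a geroprotective-intervention
#' contrast (treated vs aged control; the old heterochronic parabiont counts
#' here), `AGING` for an old-vs-young reference, `YPAR` for the young
#' heterochronic parabiont (which recapitulates, rather than reverses, the
#' aging signature), `CI` for a chronic-inflammation disease model in young
#' animals, and `OTHER` for anything else.
#'
#' @param study_id Study label.
#' @param group Contrast label (e.g. "treated_vs_old", "old_vs_young").
#' @param unit Organ (bulk) or cell-type (single-cell) label.
#' @param modality `"bulk"` or `"single_cell"`.
#' @param role One of `"GI"`, `"AGING"`, `"YPAR"`, `"CI"`, `"OTHER"`.
#' @param intervention Intervention label for GI/YPAR contexts
#'   (e.g. "senolysis"); empty string otherwise.
#' @return An object of class `"context_key"`.
#' @examples
#' context_key("seno2017", "treated_vs_old", "liver", "bulk", "GI", "senolysis")
#' @export
context_key <- function(study_id, group, unit,
                        modality = c("bulk", "single_cell"),
                        role = c("GI", "AGING", "YPAR", "CI", "OTHER"),
                        intervention = "") {
  modality <- match.arg(modality)
  role <- match.arg(role)
  for (f in list(study_id = study_id, group = group, unit = unit,
                 intervention = intervention)) {
    if (!is.character(f) || length(f) != 1L || is.na(f))
      stopf("context fields must be single character strings")
  }
  if (!nzchar(study_id) || !nzchar(group) || !nzchar(unit))
    stopf("study_id, group and unit must be non-empty")
  structure(
    list(study_id = study_id, group = group, unit = unit,
         modality = modality, role = role, intervention = intervention),
    class = "context_key"
  )
}

#' @export
format.context_key <- function(x, ...) {
  paste(x$study_id, x$group, x$unit, sep = "|")
}

#' @export
print.context_key <- function(x, ...) {
  cat(sprintf("<context> %s  [%s, %s%s]\n", format(x), x$modality, x$role,
              if (nzchar(x$intervention)) paste0(", ", x$intervention) else ""))
  invisible(x)
}

#' Unique identifier of a context
#'
#' `study_id|group|unit`, the triple required to be unique within a run.
#' @param ctx A [context_key()].
#' @return A string.
#' @export
context_id <- function(ctx) {
  stopifnot(inherits(ctx, "context_key"))
  format(ctx)
}

context_fields <- c("study_id", "group", "unit", "modality", "role",
                    "intervention")

#' Read or write a context manifest
#'
#' A manifest is a tab-separated file with columns `study_id`, `group`,
#' `unit`, `modality`, `role`, `intervention`, `path`, one row per signature
#' table. Paths are interpreted relative to the manifest's own directory
#' unless absolute.
#'
#' @param path Manifest file path.
#' @return `read_manifest()`: a data.frame with the manifest columns plus a
#'   resolved `path`; `write_manifest()`: the path, invisibly.
#' @export
read_manifest <- function(path) {
  m <- read_tsv(path)
  need <- c(context_fields, "path")
  miss <- setdiff(need, names(m))
  if (length(miss)) stopf("manifest lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(m) == 0L) stopf("manifest is empty: %s", path)
  bad_mod <- setdiff(unique(m$modality), c("bulk", "single_cell"))
  if (length(bad_mod)) stopf("unknown modality: %s", paste(bad_mod, collapse = ", "))
  bad_role <- setdiff(unique(m$role), c("GI", "AGING", "YPAR", "CI", "OTHER"))
  if (length(bad_role)) stopf("unknown role: %s", paste(bad_role, collapse = ", "))
  key <- paste(m$study_id, m$group, m$unit, sep = "|")
  if (anyDuplicated(key))
    stopf("duplicate context in manifest: %s", key[duplicated(key)][1L])
  m$intervention[is.na(m$intervention)] <- ""
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' @rdname read_manifest
#' @param manifest Data.frame of context rows (columns as above).
#' @export
write_manifest <- function(manifest, path) {
  need <- c(context_fields, "path")
  stopifnot(all(need %in% names(manifest)))
  write_tsv(manifest[, need], path)
}

manifest_context <- function(row) {
  context_key(row$study_id, row$group, row$unit, row$modality, row$role,
              row$intervention %||% "")
}
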