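# Orchestration: manifest + config -> DEG selection -> ambient hygiene ->
# correlation -> convergence -> enrichment & scores -> CI maps -> clock.
# Stage outputs are pure functions of (inputs, config, seed); rerunning
# with the same seed reproduces every file byte for byte.

#' Default run configuration
#'
#' All defaults equal the meta-analysis parameters housed in the stage
#' functions: DEG thresholds |FC| > 1.25 / FDR < 0.05, pair exclusion below
#' 10 shared DEGs, p < 0.05 presentation mask, intervention context-count
#' rules (senolysis 1, caloric restriction 2, reprogramming 2, parabiosis
#' 3), sharing threshold k = 3, ORA filters (min overlap 2, p < 0.01,
#' enrichment >= 1.5, FDR < 0.01), score weights (organ 1, parabiosis cell
#' type 0.5), ambient bounds (top 5 markers / top 50 expressed).
#'
#' @return Nested list of class `"run_config"`.
#' @export
default_config <- function() {
  structure(list(
    thresholds = list(min_abs_fc = 1.25, max_fdr = 0.05),
    min_shared = 10,
    alpha = 0.05,
    intervention_rules = list(
      list(intervention = "senolysis", min_contexts = 1),
      list(intervention = "caloric_restriction", min_contexts = 2),
      list(intervention = "reprogramming", min_contexts = 2),
      list(intervention = "parabiosis", min_contexts = 3)),
    k_shared = 3,
    ora = list(min_overlap = 2, p_cutoff = 0.01, min_enrichment = 1.5,
               fdr_cutoff = 0.01),
    score_weights = list(organ = 1, parabiosis_celltype = 0.5),
    ambient = list(top_markers = 5, top_expressed = 50),
    clock = list(scale_method = "zscore", collision_policy = "sum"),
    seed = 1), class = "run_config")
}

merge_validate <- function(user, defaults, prefix, errors) {
  unknown <- setdiff(names(user), names(defaults))
  for (k in unknown)
    errors <- c(errors, sprintf("unknown key '%s%s'", prefix, k))
  out <- defaults
  for (k in intersect(names(user), names(defaults))) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      res <- merge_validate(user[[k]], defaults[[k]],
                            paste0(prefix, k, "."), errors)
      out[[k]] <- res$value
      errors <- res$errors
    } else {
      out[[k]] <- user[[k]]
    }
  }
  list(value = out, errors = errors)
}

#' Validate a run configuration
#'
#' Accepts a YAML file path or a list; fills defaults, rejects unknown
#' keys, and checks every constraint, reporting all violations at once.
#'
#' @param config YAML file path, list of overrides, or `NULL` for pure
#'   defaults.
#' @return A validated `"run_config"`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  if (is.null(config)) config <- list()
  if (inherits(config, "run_config")) config <- unclass(config)
  defaults <- unclass(default_config())
  # intervention_rules is replaced wholesale, not key-merged
  rules <- config$intervention_rules %||% defaults$intervention_rules
  config$intervention_rules <- NULL
  defaults$intervention_rules <- NULL
  res <- merge_validate(config, defaults, "", character(0))
  cfg <- res$value
  cfg$intervention_rules <- rules
  errors <- res$errors
  chk <- function(expr) {
    e <- tryCatch({ expr; NULL }, error = function(e) conditionMessage(e))
    if (!is.null(e)) errors <<- c(errors, e)
  }
  chk(deg_thresholds(cfg$thresholds$min_abs_fc, cfg$thresholds$max_fdr))
  chk(check_count(cfg$min_shared, "min_shared", min = 2L))
  chk(check_number(cfg$alpha, "alpha", lower = 0, upper = 1,
                   strict_lower = TRUE, strict_upper = TRUE))
  chk(check_count(cfg$k_shared, "k_shared", min = 1L))
  chk(check_count(cfg$ora$min_overlap, "ora.min_overlap", min = 1L))
  chk(check_number(cfg$ora$p_cutoff, "ora.p_cutoff", lower = 0, upper = 1,
                   strict_lower = TRUE))
  chk(check_number(cfg$ora$min_enrichment, "ora.min_enrichment", lower = 0))
  chk(check_number(cfg$ora$fdr_cutoff, "ora.fdr_cutoff", lower = 0,
                   upper = 1, strict_lower = TRUE))
  chk(check_number(cfg$score_weights$organ, "score_weights.organ", lower = 0))
  chk(check_number(cfg$score_weights$parabiosis_celltype,
                   "score_weights.parabiosis_celltype", lower = 0))
  chk(check_count(cfg$ambient$top_markers, "ambient.top_markers", min = 1L))
  chk(check_count(cfg$ambient$top_expressed, "ambient.top_expressed", min = 1L))
  if (!cfg$clock$scale_method %in% c("none", "zscore", "minmax"))
    errors <- c(errors, "clock.scale_method must be one of none/zscore/minmax")
  if (!cfg$clock$collision_policy %in% c("sum", "max", "error"))
    errors <- c(errors, "clock.collision_policy must be one of sum/max/error")
  chk(check_count(cfg$seed, "seed", min = 0L))
  for (r in cfg$intervention_rules) {
    if (is.null(r$intervention) || is.null(r$min_contexts)) {
      errors <- c(errors, "each intervention rule needs intervention and min_contexts")
    } else {
      chk(check_count(r$min_contexts,
                      paste0("intervention_rules[", r$intervention,
                             "].min_contexts"), min = 1L))
    }
  }
  if (length(errors))
    stopf("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

pipeline_score_weights <- function(config) {
  c(bulk = config$score_weights$organ,
    single_cell = config$score_weights$parabiosis_celltype)
}

enrich_contexts <- function(tables, meta, lib, config, thr) {
  out <- list()
  for (i in seq_along(tables)) {
    for (dir in c("up", "down")) {
      degs <- select_degs(tables[[i]], thr, dir)$gene
      res <- ora_test(degs, lib, config$ora$min_overlap,
                      config$ora$p_cutoff, config$ora$min_enrichment)
      if (nrow(res)) {
        res <- cbind(context = meta$id[i], study_id = meta$study_id[i],
                     unit = meta$unit[i], modality = meta$modality[i],
                     role = meta$role[i], intervention = meta$intervention[i],
                     direction = dir, as.data.frame(res))
        out[[length(out) + 1L]] <- res
      }
    }
  }
  if (!length(out))
    return(data.frame(context = character(0), study_id = character(0),
                      unit = character(0), modality = character(0),
                      role = character(0), intervention = character(0),
                      direction = character(0), set_id = character(0),
                      overlap = integer(0), list_size = integer(0),
                      set_size = integer(0), background_size = integer(0),
                      fold_enrichment = numeric(0), pvalue = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Run the full meta-analysis pipeline
#'
#' Reads every signature table named in the manifest, applies the
#' single-cell ambient exclusion where marker/expression-rank inputs are
#' available, and executes the correlation, convergence, enrichment/score,
#' chronic-inflammation map and clock stages, writing each stage's table
#' to `outdir` plus a machine-readable `summary.json`. All input paths are
#' checked before any computation.
#'
#' @param manifest Manifest file path (see [read_manifest()]).
#' @param config A [validate_config()] result, a path/list accepted by it,
#'   or `NULL` for defaults.
#' @param outdir Output directory (created).
#' @param inputs Named list of optional auxiliary input paths: `gmt`,
#'   `aging_genes`, `markers`, `expr_ranks`, `clock_model`, `clock_expr`,
#'   `gene_lengths`, `sample_groups`, `homologs`. Stages lacking their
#'   inputs are skipped.
#' @param quiet Suppress stage messages.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(manifest, config = NULL, outdir, inputs = list(),
                         quiet = FALSE) {
  config <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  known_inputs <- c("gmt", "aging_genes", "markers", "expr_ranks",
                    "clock_model", "clock_expr", "gene_lengths",
                    "sample_groups", "homologs")
  bad <- setdiff(names(inputs), known_inputs)
  if (length(bad)) stopf("unknown input '%s'", bad[1L])
  if (!file.exists(manifest)) stopf("missing input file: %s", manifest)
  for (nm in names(inputs))
    if (!is.null(inputs[[nm]]) && !file.exists(inputs[[nm]]))
      stopf("missing input file: %s", inputs[[nm]])
  meta <- read_manifest(manifest)
  for (p in meta$path)
    if (!file.exists(p)) stopf("missing input file: %s", p)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  thr <- deg_thresholds(config$thresholds$min_abs_fc,
                        config$thresholds$max_fdr)
  meta$id <- paste(meta$study_id, meta$group, meta$unit, sep = "|")
  tables <- lapply(seq_len(nrow(meta)), function(i)
    read_signature_table(meta$path[i], context = manifest_context(meta[i, ])))
  say("read %d signature tables (%d genes each on average)",
      length(tables), round(mean(vapply(tables, nrow, numeric(1)))))

  # -- single-cell ambient hygiene ------------------------------------
  exclusions <- data.frame(context = character(0), gene = character(0),
                           offending_cell_type = character(0),
                           marker_rank = integer(0),
                           expression_rank = integer(0),
                           stringsAsFactors = FALSE)
  if (!is.null(inputs$markers) && !is.null(inputs$expr_ranks)) {
    markers <- read_marker_table(inputs$markers)
    expr_ranks <- read_tsv(inputs$expr_ranks)
    for (i in seq_len(nrow(meta))) {
      if (meta$modality[i] != "single_cell") next
      if (!meta$unit[i] %in% markers$cell_type) next
      degs <- select_degs(tables[[i]], thr, "both")$gene
      fl <- filter_ambient_degs(degs, meta$unit[i], markers, expr_ranks,
                                config$ambient$top_markers,
                                config$ambient$top_expressed)
      if (nrow(fl$excluded)) {
        exclusions <- rbind(exclusions,
                            cbind(context = meta$id[i], fl$excluded))
        keep <- !tables[[i]]$gene %in% fl$excluded$gene
        ctx <- sig_context(tables[[i]])
        tables[[i]] <- signature_table(tables[[i]]$gene[keep],
                                       tables[[i]]$log2fc[keep],
                                       tables[[i]]$pvalue[keep],
                                       tables[[i]]$fdr[keep], context = ctx)
      }
    }
    say("ambient filter: excluded %d DEG entries across single-cell contexts",
        nrow(exclusions))
  }
  write_tsv(exclusions, file.path(outdir, "ambient_exclusions.tsv"))

  # -- DEG counts ------------------------------------------------------
  deg_counts <- data.frame(
    context = meta$id, role = meta$role, modality = meta$modality,
    n_up = vapply(tables, function(t) nrow(select_degs(t, thr, "up")), integer(1)),
    n_down = vapply(tables, function(t) nrow(select_degs(t, thr, "down")), integer(1)),
    stringsAsFactors = FALSE)
  write_tsv(deg_counts, file.path(outdir, "deg_counts.tsv"))

  # -- correlation (GI/AGING/YPAR contexts; CI models are mapped, not
  #    correlated) ------------------------------------------------------
  corr_idx <- which(meta$role != "CI")
  corr <- NULL
  blocks <- NULL
  if (length(corr_idx) >= 2L) {
    corr <- correlation_matrix(tables[corr_idx], thr,
                               min_shared = config$min_shared,
                               alpha = config$alpha)
    pairs <- as.data.frame(corr)
    write_tsv(pairs, file.path(outdir, "correlation_pairs.tsv"))
    rho_out <- data.frame(context = rownames(corr$rho), corr$rho,
                          check.names = FALSE)
    write_tsv(rho_out, file.path(outdir, "correlation_matrix.tsv"))
    blocks <- block_summary(corr, by = "role")
    write_tsv(blocks, file.path(outdir, "correlation_blocks.tsv"))
    say("correlation: %d pairs, %d excluded below %d shared DEGs",
        nrow(pairs), sum(is.na(pairs$rho)), config$min_shared)
  }

  # -- convergence -----------------------------------------------------
  report <- NULL
  memberships <- NULL
  if (!is.null(inputs$aging_genes)) {
    aging_list <- read_gene_list(inputs$aging_genes)
    build_sets <- function(direction) {
      sets <- list()
      for (r in config$intervention_rules) {
        rule <- intervention_rule(r$intervention, r$min_contexts, direction)
        idx <- which(meta$role == "GI" & meta$intervention == r$intervention)
        sets[[r$intervention]] <-
          if (length(idx)) intervention_deg_set(tables[idx], rule, thr)
          else character(0)
      }
      sets
    }
    ypar_rule_n <- 3L
    for (r in config$intervention_rules)
      if (identical(r$intervention, "parabiosis"))
        ypar_rule_n <- r$min_contexts
    build_ypar <- function(direction) {
      idx <- which(meta$role == "YPAR")
      if (!length(idx)) return(character(0))
      iv <- unique(meta$intervention[idx])[1L]
      intervention_deg_set(tables[idx],
                           intervention_rule(iv, ypar_rule_n, direction), thr)
    }
    memberships <- rbind(
      trend_intersection(build_sets("up"), build_ypar("down"), aging_list,
                         trend = "gi_up"),
      trend_intersection(build_sets("down"), build_ypar("up"), aging_list,
                         trend = "gi_down"))
    write_tsv(memberships, file.path(outdir, "trend_memberships.tsv"))
    report <- shared_gene_report(memberships, tables, k = config$k_shared)
    write_tsv(report, file.path(outdir, "shared_genes.tsv"))
    venn <- rbind(
      cbind(trend = "gi_up",
            venn_region_counts(memberships[memberships$trend == "gi_up", ])),
      cbind(trend = "gi_down",
            venn_region_counts(memberships[memberships$trend == "gi_down", ])))
    write_tsv(venn, file.path(outdir, "venn_counts.tsv"))
    say("convergence: %d genes shared by >= %d sets", nrow(report),
        config$k_shared)
  }

  # -- enrichment and rank scores -------------------------------------
  enr <- NULL
  score_cors <- NULL
  trend_scores <- list()
  if (!is.null(inputs$gmt)) {
    lib <- read_gmt(inputs$gmt)
    enr <- enrich_contexts(tables, meta, lib, config, thr)
    write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    w <- pipeline_score_weights(config)
    pick <- function(roles_dirs) {
      sel <- rep(FALSE, nrow(enr))
      for (rd in roles_dirs)
        sel <- sel | (enr$role == rd[1] & enr$direction == rd[2])
      enr[sel, , drop = FALSE]
    }
    groupings <- list(
      aging_up = list(c("AGING", "up")),
      aging_down = list(c("AGING", "down")),
      gi_down = list(c("GI", "down"), c("YPAR", "up")),
      gi_up = list(c("GI", "up"), c("YPAR", "down")))
    trend_scores <- lapply(groupings, function(g)
      pathway_rank_scores(pick(g), config$ora$fdr_cutoff, w,
                          items = names(lib$sets)))
    score_tab <- do.call(rbind, lapply(names(trend_scores), function(nm)
      if (nrow(trend_scores[[nm]]))
        cbind(trend = nm, trend_scores[[nm]]) else NULL))
    if (!is.null(score_tab))
      write_tsv(score_tab, file.path(outdir, "pathway_scores.tsv"))
    cor_pairs <- list(c("aging_up", "gi_down"), c("aging_down", "gi_up"))
    score_cors <- do.call(rbind, lapply(cor_pairs, function(p) {
      r <- tryCatch(rank_score_correlation(trend_scores[[p[1]]],
                                           trend_scores[[p[2]]]),
                    error = function(e) list(rho = NA_real_,
                                             pvalue = NA_real_, n = 0L))
      data.frame(scores_a = p[1], scores_b = p[2], rho = r$rho,
                 pvalue = r$pvalue, n = r$n, stringsAsFactors = FALSE)
    }))
    write_tsv(score_cors, file.path(outdir, "score_correlations.tsv"))
    say("enrichment: %d significant rows; aging-up vs GI-down score rho = %.3f",
        nrow(enr), score_cors$rho[1])
  }

  # -- chronic-inflammation score maps --------------------------------
  ci_genes <- NULL
  ci_paths <- NULL
  ci_idx <- which(meta$role == "CI")
  if (length(ci_idx)) {
    ci_genes <- ci_gene_scores(tables[ci_idx], thr)
    if (!is.null(report) && nrow(report)) {
      ci_genes <- overlay_report(ci_genes,
                                 report[!report$conflict, c("gene", "trend")])
    }
    write_tsv(ci_genes, file.path(outdir, "ci_gene_scores.tsv"))
    if (!is.null(enr)) {
      ci_enr <- enr[enr$role == "CI", , drop = FALSE]
      ci_paths <- ci_pathway_scores(ci_enr, config$ora$fdr_cutoff)
      gi_highlight <- do.call(rbind, lapply(c("gi_up", "gi_down"), function(nm) {
        s <- trend_scores[[nm]]
        if (is.null(s) || !nrow(s)) return(NULL)
        data.frame(item = s$item[s$score > 0], trend = nm,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(gi_highlight) && nrow(gi_highlight)) {
        gi_highlight <- gi_highlight[!duplicated(gi_highlight$item), ]
        ci_paths <- overlay_report(ci_paths, gi_highlight)
      }
      write_tsv(ci_paths, file.path(outdir, "ci_pathway_scores.tsv"))
    }
    say("chronic-inflammation maps: %d genes scored", nrow(ci_genes))
  }

  # -- transcriptomic clock -------------------------------------------
  clock_out <- NULL
  clock_tests <- NULL
  clock_in <- c("clock_model", "clock_expr", "gene_lengths", "sample_groups",
                "homologs")
  if (all(clock_in %in% names(inputs))) {
    clock <- read_clock_model(inputs$clock_model)
    counts <- read_counts(inputs$clock_expr)
    lengths <- read_gene_lengths(inputs$gene_lengths)
    groups <- read_sample_groups(inputs$sample_groups)
    hom <- read_tsv(inputs$homologs)
    expr <- expression_matrix(counts, lengths = lengths,
                              groups = groups$group[match(colnames(counts),
                                                          groups$sample)])
    expr <- map_homologs(expr, hom,
                         collision_policy = config$clock$collision_policy)
    expr_t <- normalize_for_clock(expr,
                                  pseudocount = clock$transform$pseudocount)
    ages <- apply_clock(expr_t, clock)
    panels <- groups$panel[match(names(ages), groups$sample)]
    scaled <- scale_ages(ages, method = config$clock$scale_method,
                         panels = panels)
    clock_out <- data.frame(sample = names(ages),
                            group = expr$groups[names(ages)],
                            panel = panels,
                            raw_age_years = as.numeric(ages),
                            scaled_age = as.numeric(scaled),
                            stringsAsFactors = FALSE)
    write_tsv(clock_out, file.path(outdir, "clock_ages.tsv"))
    clock_tests <- do.call(rbind, lapply(unique(panels), function(p) {
      idx <- panels == p
      g <- clock_out$group[idx]
      if (length(unique(g)) != 2L) return(NULL)
      # delta is second group minus first, in sample-file order (so a
      # treated group listed after its control yields treated - control)
      cmp <- compare_groups(clock_out$raw_age_years[idx],
                            factor(g, levels = unique(g)))
      data.frame(panel = p, group_a = cmp$groups[1], group_b = cmp$groups[2],
                 delta_years = cmp$delta, pvalue = cmp$pvalue,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(clock_tests))
      write_tsv(clock_tests, file.path(outdir, "clock_tests.tsv"))
    say("clock: %d samples aged; %d panel comparisons", nrow(clock_out),
        if (is.null(clock_tests)) 0L else nrow(clock_tests))
  }

  # -- summary ---------------------------------------------------------
  block_rec <- function(a, b) {
    if (is.null(blocks)) return(NULL)
    r <- blocks[blocks$block_a == a & blocks$block_b == b, ]
    if (!nrow(r)) return(NULL)
    list(mean_rho = r$mean_rho, n_significant = r$n_significant,
         frac_negative = r$frac_negative, frac_positive = r$frac_positive)
  }
  summary <- list(
    seed = config$seed,
    n_contexts = nrow(meta),
    n_degs_total = sum(deg_counts$n_up + deg_counts$n_down),
    n_ambient_excluded = nrow(exclusions),
    correlation = list(
      gi_aging = block_rec("AGING", "GI"),
      aging_aging = block_rec("AGING", "AGING"),
      gi_gi = block_rec("GI", "GI"),
      ypar_aging = block_rec("AGING", "YPAR")),
    convergence = if (!is.null(report)) list(
      k = config$k_shared,
      n_shared_genes = nrow(report),
      n_gi_up = sum(report$trend == "gi_up"),
      n_gi_down = sum(report$trend == "gi_down"),
      n_conflict = sum(report$conflict)),
    pathway_score_correlations = if (!is.null(score_cors))
      stats::setNames(as.list(score_cors$rho),
                      paste(score_cors$scores_a, "vs", score_cors$scores_b)),
    clock = if (!is.null(clock_tests))
      lapply(seq_len(nrow(clock_tests)), function(i)
        list(panel = clock_tests$panel[i],
             delta_years = clock_tests$delta_years[i],
             pvalue = clock_tests$pvalue[i])))
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

#' Simulate a study collection and run the full pipeline on it
#'
#' Convenience wrapper used by the recovery tests: writes a synthetic study
#' under `dir/inputs` (see [write_synthetic_study()]) and runs
#' [run_pipeline()] on it into `dir/results`. Both halves are driven by the
#' configuration seed, so repeated calls are byte-identical.
#'
#' @param dir Run directory.
#' @param config Configuration accepted by [validate_config()].
#' @param ... Generator overrides passed to [write_synthetic_study()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, list with the generator output (`synthetic`) and the
#'   pipeline `summary`.
#' @export
run_synthetic_study <- function(dir, config = NULL, ..., quiet = FALSE) {
  config <- validate_config(config)
  syn <- write_synthetic_study(file.path(dir, "inputs"),
                               seed = config$seed, ...)
  paths <- syn$paths
  inputs <- paths[!vapply(paths, is.null, logical(1))]
  inputs$manifest <- NULL
  summary <- run_pipeline(paths$manifest, config,
                          outdir = file.path(dir, "results"),
                          inputs = inputs, quiet = quiet)
  invisible(list(synthetic = syn, summary = summary))
}
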