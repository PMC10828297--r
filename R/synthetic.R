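# Synthetic multi-study DEG data with planted ground truth.
#
# The generator emulates the meta-analysis inputs: a signed "aging program"
# of genes whose expression rises or falls with age, recapitulated by
# chronic-inflammation models and the young parabiont and reversed by
# geroprotective interventions; calibrated p-values from a known z-model;
# gene sets with planted enrichment; marker/contaminant fixtures for the
# ambient filter; and count matrices consistent with a planted linear
# clock. Every stage downstream therefore has a recovery test with known
# truth.

#' Planted ground truth for a synthetic study collection
#'
#' Draws a signed aging program: `n_program` genes with log2-scale Normal
#' effects symmetric about zero. Role sign multipliers encode the study
#' structure: aging, chronic inflammation and the young parabiont express
#' the program with sign +1, geroprotective interventions reverse it
#' (sign -1), and `OTHER` contexts carry no signal.
#'
#' Observed log2 fold-changes are later simulated as
#' `sign x effect + Normal(0, noise_sd / sqrt(n_samples_equiv))`, so
#' `noise_sd` is the per-sample fold-change noise and `n_samples_equiv`
#' plays the role of a group size.
#'
#' @param n_genes Size of the gene universe.
#' @param n_program Number of program genes (`<= n_genes`).
#' @param effect_sd Standard deviation of program effects (log2 units).
#' @param noise_sd Fold-change noise standard deviation (log2 units).
#' @param n_samples_equiv Effective group size dividing the noise.
#' @param seed Integer seed; identical seeds give identical truth.
#' @return Object of class `"ground_truth"` with fields `genes`,
#'   `program` (named effect vector), `reversal_map`, `noise_sd`,
#'   `n_samples_equiv`, `seed`.
#' @export
generate_ground_truth <- function(n_genes = 1000, n_program = 100,
                                  effect_sd = 2, noise_sd = 0.2,
                                  n_samples_equiv = 4, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_program <- check_count(n_program, "n_program", min = 1L)
  if (n_program > n_genes) stopf("n_program must not exceed n_genes")
  check_number(effect_sd, "effect_sd", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_count(n_samples_equiv, "n_samples_equiv", min = 1L)
  genes <- sprintf("G%06d", seq_len(n_genes))
  with_seed(seed, {
    program_genes <- sort(sample(genes, n_program))
    effects <- stats::setNames(stats::rnorm(n_program, 0, effect_sd),
                               program_genes)
  })
  structure(list(
    genes = genes,
    program = effects,
    reversal_map = c(AGING = 1, CI = 1, YPAR = 1, GI = -1, OTHER = 0),
    noise_sd = noise_sd,
    n_samples_equiv = n_samples_equiv,
    effect_sd = effect_sd,
    seed = as.integer(seed)),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d genes, %d program genes (%d up / %d down), noise_sd %g\n",
              length(x$genes), length(x$program), sum(x$program > 0),
              sum(x$program < 0), x$noise_sd))
  invisible(x)
}

#' Signed reference list of the planted aging program
#'
#' The synthetic analogue of a published global-aging-gene list: every
#' program gene with its aging direction (`up` for positive effect).
#'
#' @param truth A [generate_ground_truth()] object.
#' @return Data.frame `gene`, `direction`.
#' @export
truth_aging_list <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  data.frame(gene = names(truth$program),
             direction = ifelse(truth$program > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Simulate one context's signature table
#'
#' log2FC = role sign x effect + Normal(0, se) for program genes and
#' Normal(0, se) otherwise, with `se = noise_sd / sqrt(n_samples_equiv)`.
#' P-values are two-sided normal tail probabilities of the observed
#' fold-change under the noise model, so null genes are exactly uniform;
#' the BH-adjusted column is filled. With `noise_sd = 0` fold-changes are
#' exact and p is 0 for program genes, 1 otherwise.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param context A [context_key()]; its role must be covered by the
#'   truth's reversal map.
#' @param n_samples_equiv Optional override of the truth's group size.
#' @param seed Integer seed.
#' @return A `signature_table` carrying `context`.
#' @export
simulate_signature <- function(truth, context, n_samples_equiv = NULL,
                               seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(context, "context_key"))
  if (!context$role %in% names(truth$reversal_map))
    stopf("role '%s' not covered by the reversal map", context$role)
  sgn <- truth$reversal_map[[context$role]]
  nse <- n_samples_equiv %||% truth$n_samples_equiv
  se <- truth$noise_sd / sqrt(nse)
  mu <- stats::setNames(numeric(length(truth$genes)), truth$genes)
  mu[names(truth$program)] <- sgn * truth$program
  if (se == 0) {
    lfc <- mu
    p <- ifelse(mu == 0, 1, 0)
  } else {
    lfc <- mu + with_seed(seed, stats::rnorm(length(mu), 0, se))
    p <- 2 * stats::pnorm(-abs(lfc) / se)
  }
  signature_table(truth$genes, unname(lfc), unname(p), context = context)
}

#' Simulate a gene-set library with planted enrichment
#'
#' Planted sets draw `planted_frac` of their members from the aging
#' program (direction-specific: "up" sets from positive-effect program
#' genes, "down" sets from negative) and the rest uniformly from the
#' remaining universe; null sets are uniform draws. The background is the
#' full gene universe. Planted directions alternate up/down across the
#' planted sets.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param n_sets Total number of sets.
#' @param set_size Members per set (`<= n_genes`).
#' @param planted_frac Fraction of planted-set members from the program.
#' @param n_planted Number of planted sets (`<= n_sets`).
#' @param seed Integer seed.
#' @return A [gene_set_library()] with attribute `"planted"`, a data.frame
#'   `set_id`, `direction`.
#' @export
simulate_gene_sets <- function(truth, n_sets = 20, set_size = 40,
                               planted_frac = 0.5, n_planted = 6, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  n_sets <- check_count(n_sets, "n_sets", min = 1L)
  set_size <- check_count(set_size, "set_size", min = 1L)
  if (set_size > length(truth$genes)) stopf("set_size exceeds the universe")
  check_number(planted_frac, "planted_frac", lower = 0, upper = 1)
  n_planted <- check_count(n_planted, "n_planted", min = 0L)
  if (n_planted > n_sets) stopf("n_planted must not exceed n_sets")
  up_pool <- names(truth$program)[truth$program > 0]
  down_pool <- names(truth$program)[truth$program < 0]
  sets <- list()
  planted <- data.frame(set_id = character(0), direction = character(0),
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    for (i in seq_len(n_planted)) {
      dir <- if (i %% 2L == 1L) "up" else "down"
      pool <- if (dir == "up") up_pool else down_pool
      k <- min(round(planted_frac * set_size), length(pool))
      core <- sample(pool, k)
      rest <- sample(setdiff(truth$genes, core), set_size - k)
      id <- sprintf("SET_%s_%02d", toupper(dir), i)
      sets[[id]] <- c(core, rest)
      planted <- rbind(planted, data.frame(set_id = id, direction = dir,
                                           stringsAsFactors = FALSE))
    }
    for (i in seq_len(n_sets - n_planted)) {
      sets[[sprintf("SET_NULL_%02d", i)]] <- sample(truth$genes, set_size)
    }
  })
  lib <- gene_set_library(sets, truth$genes)
  attr(lib, "planted") <- planted
  lib
}

#' Synthetic linear clock for tests
#'
#' Coefficients drawn Normal(0, `coef_sd`) over `n_genes` synthetic human
#' symbols, intercept at the middle of the intended age range so the
#' constructible expression stays on a realistic abundance scale.
#'
#' @param n_genes Number of clock genes.
#' @param intercept Years.
#' @param coef_sd Coefficient scale (years per transformed unit).
#' @param pseudocount Transform pseudocount.
#' @param seed Integer seed.
#' @param gene_prefix Symbol prefix (default "HCLK").
#' @return A [clock_model()].
#' @export
make_synthetic_clock <- function(n_genes = 30, intercept = 50, coef_sd = 1,
                                 pseudocount = 1, seed = 1,
                                 gene_prefix = "HCLK") {
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  genes <- sprintf("%s%03d", gene_prefix, seq_len(n_genes))
  coefs <- with_seed(seed, stats::rnorm(n_genes, 0, coef_sd))
  clock_model(intercept, stats::setNames(coefs, genes),
              pseudocount = pseudocount)
}

#' Simulate expression recovered exactly by a linear clock
#'
#' Constructs a count matrix such that the full clock protocol
#' ([normalize_for_clock()] then [apply_clock()]) returns `true_ages`
#' exactly when `noise_sd = 0`. Per sample the required clock signal is
#' solved in transformed space and distributed over same-sign coefficient
#' genes proportionally to their coefficients; background genes absorb the
#' sequencing-depth budget so FPKM normalization inverts exactly. Noise is
#' added in transformed space before inversion.
#'
#' @param clock A [clock_model()].
#' @param true_ages Numeric vector of target ages (years, `>= 0`).
#' @param noise_sd Noise on transformed expression (0 = exact recovery).
#' @param seed Integer seed (used for gene lengths and noise).
#' @param n_background Number of non-clock filler genes.
#' @return An [expression_matrix()] (units `"counts"`) with samples
#'   `S01`, `S02`, ...
#' @export
simulate_clock_expression <- function(clock, true_ages, noise_sd = 0,
                                      seed = 1, n_background = 50) {
  stopifnot(inherits(clock, "clock_model"))
  if (any(true_ages < 0)) stopf("ages must be >= 0")
  check_number(noise_sd, "noise_sd", lower = 0)
  coefs <- clock$coefficients
  pc <- clock$transform$pseudocount
  floor_t <- log2(pc)
  n_c <- length(coefs)
  n_s <- length(true_ages)
  pos <- which(coefs > 0); neg <- which(coefs < 0)
  B <- sum(coefs)
  Tmat <- matrix(floor_t, n_c, n_s,
                 dimnames = list(names(coefs), sprintf("S%02d", seq_len(n_s))))
  for (j in seq_len(n_s)) {
    v <- true_ages[j] - clock$intercept - floor_t * B
    if (v >= 0) {
      if (!length(pos))
        stopf("cannot construct: age %g needs positive coefficients",
              true_ages[j])
      s <- v / sum(coefs[pos]^2)
      Tmat[pos, j] <- floor_t + coefs[pos] * s
    } else {
      if (!length(neg))
        stopf("cannot construct: age %g needs negative coefficients",
              true_ages[j])
      s <- v / sum(coefs[neg]^2)
      Tmat[neg, j] <- floor_t + coefs[neg] * s
    }
  }
  bg_genes <- sprintf("BG%04d", seq_len(n_background))
  all_genes <- c(names(coefs), bg_genes)
  with_seed(seed, {
    lengths <- stats::setNames(
      round(stats::runif(length(all_genes), 500, 5000)), all_genes)
    if (noise_sd > 0)
      Tmat <- pmax(Tmat + stats::rnorm(length(Tmat), 0, noise_sd), floor_t)
  })
  len_kb <- lengths / 1000
  fpkm_clock <- 2^Tmat - pc
  counts <- matrix(0, length(all_genes), n_s,
                   dimnames = list(all_genes, colnames(Tmat)))
  for (j in seq_len(n_s)) {
    used <- sum(fpkm_clock[, j] * len_kb[names(coefs)])
    if (used >= 1e6)
      stopf("cannot construct: clock signal exceeds the FPKM budget; bring ages closer to the intercept or enlarge coefficients")
    bg_fpkm <- (1e6 - used) / sum(len_kb[bg_genes])
    fpkm <- c(fpkm_clock[, j], rep(bg_fpkm, n_background))
    # depth 1e6 makes counts = fpkm * len_kb with total exactly 1e6
    counts[, j] <- fpkm * len_kb
  }
  expression_matrix(counts, lengths = lengths, units = "counts")
}

#' Marker/expression fixture with planted ambient contaminants
#'
#' Builds ranked marker lists per cell type, a dataset-wide expression
#' ranking (plus a count matrix consistent with it), and per-cell-type DEG
#' lists in which known "contaminant" genes satisfy both ambient-exclusion
#' criteria for the target cell type: they are top-5 markers of another
#' cell type and sit inside the top-50 expressed genes. The fixture also
#' plants near-misses (a foreign top marker with low expression, a highly
#' expressed own marker) that must survive the filter.
#'
#' @param n_celltypes Number of cell types (`>= 2`).
#' @param n_genes Universe size (ignored when `genes` given).
#' @param n_markers Markers per cell type.
#' @param n_contaminants Planted contaminants in the target DEG list.
#' @param seed Integer seed.
#' @param genes Optional gene universe to build on.
#' @param cell_types Optional cell-type labels.
#' @param contaminant_pool Optional genes preferred as contaminants (they
#'   are made foreign markers and highly expressed).
#' @return List: `markers` ([marker_table()]), `expr_ranks`, `counts`,
#'   `degs` (named list per cell type), `contaminants`, `target`
#'   (the cell type whose DEG list carries the contaminants),
#'   `cell_types`.
#' @export
simulate_marker_fixture <- function(n_celltypes = 3, n_genes = 200,
                                    n_markers = 10, n_contaminants = 3,
                                    seed = 1, genes = NULL,
                                    cell_types = NULL,
                                    contaminant_pool = NULL) {
  n_celltypes <- check_count(n_celltypes, "n_celltypes", min = 2L)
  if (is.null(genes)) genes <- sprintf("MG%04d", seq_len(n_genes))
  n_genes <- length(genes)
  if (n_genes < n_celltypes * n_markers + 60L)
    stopf("gene universe too small for the fixture")
  cell_types <- cell_types %||% sprintf("CT%d", seq_len(n_celltypes))
  stopifnot(length(cell_types) == n_celltypes)
  with_seed(seed, {
    shuffled <- sample(genes)
    # contaminants become top-5 markers of a non-target cell type
    pool <- intersect(contaminant_pool %||% character(0), genes)
    contaminants <- if (length(pool) >= n_contaminants)
      sample(pool, n_contaminants) else utils::head(shuffled, n_contaminants)
    rest <- setdiff(shuffled, contaminants)
    markers <- list()
    taken <- character(0)
    for (ct_i in seq_len(n_celltypes)) {
      mg <- rest[seq_len(n_markers) + (ct_i - 1L) * n_markers]
      markers[[cell_types[ct_i]]] <- mg
      taken <- c(taken, mg)
    }
    # overwrite: plant each contaminant as a rank <= 5 marker of a
    # non-target cell type (round-robin over cell types 2..n)
    for (i in seq_along(contaminants)) {
      ct <- cell_types[2L + (i - 1L) %% (n_celltypes - 1L)]
      slot <- 1L + (i - 1L) %/% (n_celltypes - 1L)
      if (slot > 5L) stopf("too many contaminants for top-5 marker slots")
      markers[[ct]][slot] <- contaminants[i]
    }
    target <- cell_types[1L]
    # a foreign rank <= 5 marker kept OUT of the expressed top 50
    near_miss <- setdiff(markers[[cell_types[2L]]][seq_len(5L)],
                         contaminants)[1L]
    own_top <- markers[[target]][1L]
    marker_genes <- unique(unlist(markers))
    nonmarkers <- setdiff(genes, marker_genes)
    clean_degs <- sample(nonmarkers, 5L)
    # expression order: contaminants and the target's own top marker in
    # the top 50; the near-miss and clean DEGs beyond it
    high_fill <- sample(setdiff(nonmarkers, clean_degs))
    top50 <- c(contaminants, own_top,
               utils::head(high_fill, 50L - length(contaminants) - 1L))
    low <- sample(setdiff(genes, top50))
    low <- c(setdiff(low, c(near_miss, clean_degs)), near_miss, clean_degs)
    ord <- c(top50, sample(low))
    degs <- stats::setNames(vector("list", n_celltypes), cell_types)
    degs[[target]] <- sort(c(contaminants, near_miss, own_top, clean_degs))
    for (ct in cell_types[-1L]) degs[[ct]] <- sort(sample(nonmarkers, 5L))
  })
  marker_df <- do.call(rbind, lapply(cell_types, function(ct) {
    data.frame(cell_type = ct, gene = markers[[ct]],
               rank = seq_len(n_markers),
               statistic = round(seq(3, 1, length.out = n_markers), 4),
               stringsAsFactors = FALSE)
  }))
  expr_ranks <- data.frame(gene = ord, total = (n_genes:1) / n_genes,
                           rank = seq_len(n_genes), stringsAsFactors = FALSE)
  counts <- matrix(rep(n_genes:1, 10L), n_genes, 10L,
                   dimnames = list(ord, sprintf("cell%02d", 1:10)))
  list(markers = marker_table(marker_df), expr_ranks = expr_ranks,
       counts = counts, degs = degs, contaminants = sort(contaminants),
       target = target, cell_types = cell_types)
}

# deterministic seed fan-out; stays far below 2^31
derive_seed <- function(seed, i) {
  ((as.numeric(seed) %% 1000003) * 1013 + i * 7 + 11) %% 2147483647
}

default_study_design <- function(include_ci = TRUE) {
  rows <- list(
    list("seno", "treated_vs_old", "liver", "bulk", "GI", "senolysis"),
    list("seno", "treated_vs_old", "lung", "bulk", "GI", "senolysis"),
    list("cr", "restricted_vs_old", "liver", "bulk", "GI", "caloric_restriction"),
    list("cr", "restricted_vs_old", "muscle", "bulk", "GI", "caloric_restriction"),
    list("osk", "reprogrammed_vs_old", "skin", "bulk", "GI", "reprogramming"),
    list("osk", "reprogrammed_vs_old", "kidney", "bulk", "GI", "reprogramming"),
    list("tms", "old_vs_young", "liver", "bulk", "AGING", ""),
    list("tms", "old_vs_young", "lung", "bulk", "AGING", ""),
    list("tms", "old_vs_young", "muscle", "bulk", "AGING", ""),
    list("tms", "old_vs_young", "skin", "bulk", "AGING", ""))
  sc_units <- c("hepatocyte", "endothelial", "kupffer_cell", "t_cell")
  for (u in sc_units) {
    rows <- c(rows, list(
      list("parab", "het_vs_iso_old", u, "single_cell", "GI", "parabiosis"),
      list("parab", "het_vs_iso_young", u, "single_cell", "YPAR", "parabiosis"),
      list("parab", "iso_old_vs_young", u, "single_cell", "AGING", "")))
  }
  if (include_ci) {
    for (u in c("lung", "liver", "kidney")) {
      rows <- c(rows, list(
        list("ci_bulk", "disease_vs_control", u, "bulk", "CI", ""),
        list("ci_sc", "disease_vs_control", u, "single_cell", "CI", "")))
    }
  }
  do.call(rbind, lapply(rows, function(r)
    data.frame(study_id = r[[1]], group = r[[2]], unit = r[[3]],
               modality = r[[4]], role = r[[5]], intervention = r[[6]],
               stringsAsFactors = FALSE)))
}

#' Write a complete synthetic study collection to disk
#'
#' Emits everything the pipeline consumes: per-context signature tables
#' and their manifest, a GMT gene-set library with planted enrichment, the
#' signed synthetic aging-gene list, a marker/expression fixture for the
#' ambient filter (cell types matching the single-cell units), and a
#' planted linear clock with mouse-symbol expression, gene lengths, sample
#' groups and a homolog map. All outputs are plain text and byte-identical
#' under a fixed seed.
#'
#' The default design has 2 organs each for senolysis, caloric restriction
#' and reprogramming, 4 parabiosis cell types (old and young parabionts
#' plus single-cell aging), 4 bulk aging organs, and 3 chronic-inflammation
#' models at bulk and single-cell level.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed controlling everything.
#' @param n_genes,n_program,effect_sd,noise_sd,n_samples_equiv Ground-truth
#'   parameters, see [generate_ground_truth()].
#' @param n_sets,set_size,planted_frac,n_planted Gene-set parameters, see
#'   [simulate_gene_sets()].
#' @param include_ci Include chronic-inflammation contexts.
#' @param include_clock Emit the clock bundle.
#' @param clock_shift_years Planted age reduction of the GI clock group
#'   (default -10).
#' @param clock_noise_sd Transformed-expression noise of the clock bundle.
#' @return Invisibly, a list with the `truth`, planted `library`, the
#'   marker `fixture`, the `clock`, and all file `paths` (manifest first).
#' @export
write_synthetic_study <- function(dir, seed = 1,
                                  n_genes = 1000, n_program = 100,
                                  effect_sd = 2, noise_sd = 0.2,
                                  n_samples_equiv = 4,
                                  n_sets = 20, set_size = 40,
                                  planted_frac = 0.5, n_planted = 6,
                                  include_ci = TRUE, include_clock = TRUE,
                                  clock_shift_years = -10,
                                  clock_noise_sd = 0.3) {
  dir.create(file.path(dir, "signatures"), recursive = TRUE,
             showWarnings = FALSE)
  truth <- generate_ground_truth(n_genes, n_program, effect_sd, noise_sd,
                                 n_samples_equiv, seed = seed)
  design <- default_study_design(include_ci)
  design$path <- sprintf("signatures/ctx_%02d.tsv", seq_len(nrow(design)))
  for (i in seq_len(nrow(design))) {
    ctx <- manifest_context(design[i, ])
    tab <- simulate_signature(truth, ctx, seed = derive_seed(seed, i))
    write_signature_table(tab, file.path(dir, design$path[i]))
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  write_manifest(design, manifest_path)
  lib <- simulate_gene_sets(truth, n_sets, set_size, planted_frac,
                            n_planted, seed = derive_seed(seed, 1001))
  write_gmt(lib, file.path(dir, "sets.gmt"))
  write_gene_list(truth_aging_list(truth), file.path(dir, "aging_genes.tsv"))
  sc_units <- sort(unique(design$unit[design$modality == "single_cell" &
                                        design$role != "CI"]))
  fixture <- NULL
  if (length(sc_units) >= 2L) {
    fixture <- simulate_marker_fixture(
      n_celltypes = length(sc_units), genes = truth$genes,
      cell_types = sc_units, n_contaminants = 3,
      seed = derive_seed(seed, 1002),
      contaminant_pool = names(truth$program))
    write_tsv(as.data.frame(fixture$markers), file.path(dir, "markers.tsv"))
    write_tsv(fixture$expr_ranks[, c("gene", "rank")],
              file.path(dir, "expr_ranks.tsv"))
  }
  paths <- list(manifest = manifest_path,
                gmt = file.path(dir, "sets.gmt"),
                aging_genes = file.path(dir, "aging_genes.tsv"),
                markers = if (!is.null(fixture)) file.path(dir, "markers.tsv"),
                expr_ranks = if (!is.null(fixture)) file.path(dir, "expr_ranks.tsv"))
  clock <- NULL
  if (include_clock) {
    clock <- make_synthetic_clock(seed = derive_seed(seed, 1003))
    groups <- data.frame(
      sample = sprintf("S%02d", 1:12),
      group = rep(c("old_control", "gi_treated"), each = 6),
      panel = "liver", stringsAsFactors = FALSE)
    ages <- ifelse(groups$group == "old_control", 70, 70 + clock_shift_years)
    expr <- simulate_clock_expression(clock, ages,
                                      noise_sd = clock_noise_sd,
                                      seed = derive_seed(seed, 1004))
    # present the matrix under mouse-style symbols resolved by the map
    human <- rownames(expr$counts)
    mouse <- paste0("m", tolower(human))
    map <- data.frame(source = mouse, target = human,
                      stringsAsFactors = FALSE)
    counts <- expr$counts; rownames(counts) <- mouse
    lengths <- stats::setNames(expr$lengths, mouse)
    write_clock_model(clock, file.path(dir, "clock_model.tsv"))
    write_tsv(data.frame(gene = mouse, round(counts, 6),
                         check.names = FALSE),
              file.path(dir, "clock_expr.tsv"))
    write_tsv(data.frame(gene = mouse, length = unname(lengths)),
              file.path(dir, "gene_lengths.tsv"))
    write_tsv(groups, file.path(dir, "sample_groups.tsv"))
    write_tsv(map, file.path(dir, "homologs.tsv"))
    paths <- c(paths, list(clock_model = file.path(dir, "clock_model.tsv"),
                           clock_expr = file.path(dir, "clock_expr.tsv"),
                           gene_lengths = file.path(dir, "gene_lengths.tsv"),
                           sample_groups = file.path(dir, "sample_groups.tsv"),
                           homologs = file.path(dir, "homologs.tsv")))
  }
  invisible(list(truth = truth, library = lib, fixture = fixture,
                 clock = clock, design = design, paths = paths))
}
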