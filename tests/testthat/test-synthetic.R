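test_that("ground truth is seed-deterministic with symmetric effects", {
  t1 <- generate_ground_truth(seed = 7)
  t2 <- generate_ground_truth(seed = 7)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
  expect_false(identical(t1$program, generate_ground_truth(seed = 8)$program))
  # symmetric draw: roughly half the program effects are positive
  t3 <- generate_ground_truth(n_genes = 1000, n_program = 100,
                              effect_sd = 1, seed = 7)
  expect_length(t3$program, 100)
  expect_gt(sum(t3$program > 0), 30)
  expect_lt(sum(t3$program > 0), 70)
  # boundary: every gene in the program
  tb <- generate_ground_truth(n_genes = 10, n_program = 10, seed = 1)
  expect_setequal(names(tb$program), tb$genes)
  expect_error(generate_ground_truth(n_genes = 10, n_program = 11),
               "must not exceed")
})

test_that("noise-free signatures are exact sign-flipped copies of the program", {
  truth <- generate_ground_truth(n_genes = 200, n_program = 40,
                                 noise_sd = 0, seed = 3)
  gi <- simulate_signature(truth, context_key("s", "g", "liver", "bulk",
                                              "GI", "senolysis"), seed = 1)
  ag <- simulate_signature(truth, context_key("s", "g2", "liver", "bulk",
                                              "AGING"), seed = 2)
  prog <- names(truth$program)
  expect_equal(gi$log2fc[match(prog, gi$gene)],
               -ag$log2fc[match(prog, ag$gene)])
  expect_equal(ag$log2fc[match(prog, ag$gene)], unname(truth$program))
  # non-program genes: zero fold-change, p = 1
  null_genes <- setdiff(truth$genes, prog)
  expect_true(all(gi$log2fc[match(null_genes, gi$gene)] == 0))
  expect_true(all(gi$pvalue[match(null_genes, gi$gene)] == 1))
  expect_error(simulate_signature(truth, context_key("s", "g", "x", "bulk",
                                                     "OTHER")), NA)
  # identical call twice: identical table
  gi2 <- simulate_signature(truth, context_key("s", "g", "liver", "bulk",
                                               "GI", "senolysis"), seed = 1)
  expect_identical(gi, gi2)
})

test_that("null p-values are calibrated uniform", {
  truth <- generate_ground_truth(n_genes = 10000, n_program = 100,
                                 noise_sd = 0.2, seed = 5)
  tab <- simulate_signature(truth, context_key("s", "g", "liver", "bulk",
                                               "AGING"), seed = 9)
  nulls <- tab$pvalue[!tab$gene %in% names(truth$program)]
  n <- length(nulls)
  for (alpha in c(0.01, 0.05, 0.2)) {
    se3 <- 3 * sqrt(alpha * (1 - alpha) / n)
    expect_lt(abs(mean(nulls < alpha) - alpha), se3)
  }
})

test_that("intervention and aging signatures anticorrelate over the program", {
  # empirical quantile over 100 seeds was <= -0.99; the frozen bound is -0.8
  for (s in 1:5) {
    truth <- generate_ground_truth(noise_sd = 0.2, seed = s)
    gi <- simulate_signature(truth, context_key("a", "g", "liver", "bulk",
                                                "GI", "x"), seed = s * 3 + 1)
    ag <- simulate_signature(truth, context_key("b", "g", "liver", "bulk",
                                                "AGING"), seed = s * 3 + 2)
    rho <- spearman_pair(gi, ag, names(truth$program))$rho
    expect_lte(rho, -0.8)
  }
})

test_that("planted gene sets are enriched in the true program DEG list", {
  truth <- generate_ground_truth(n_genes = 1000, n_program = 100,
                                 effect_sd = 1, seed = 11)
  lib <- simulate_gene_sets(truth, n_sets = 10, set_size = 40,
                            planted_frac = 0.5, n_planted = 2, seed = 12)
  planted <- attr(lib, "planted")
  expect_equal(nrow(planted), 2)
  # ORA of the program genes themselves: planted sets exceed the 0.01 bar,
  # p agreeing with the enumeration oracle
  res <- ora_test(names(truth$program), lib, min_overlap = 1, p_cutoff = 1.1,
                  min_enrichment = 0)
  for (sid in planted$set_id) {
    row <- res[res$set_id == sid, ]
    expect_lt(row$pvalue, 0.01)
    expect_equal(row$pvalue,
                 hyper_tail_oracle(row$overlap, row$set_size, 1000, 100),
                 tolerance = 1e-12)
  }
  # directional composition: an "up" set draws its core from positive effects
  up_id <- planted$set_id[planted$direction == "up"]
  up_core <- intersect(lib$sets[[up_id]], names(truth$program))
  expect_gte(mean(truth$program[up_core] > 0), 0.9)
  # planted_frac = 1 with room in the pool: set entirely inside the program
  lib1 <- simulate_gene_sets(truth, n_sets = 1, set_size = 10,
                             planted_frac = 1, n_planted = 1, seed = 1)
  expect_true(all(lib1$sets[[1]] %in% names(truth$program)))
  # planted_frac = 0 behaves as a uniform draw (structural check)
  lib0 <- simulate_gene_sets(truth, n_sets = 2, set_size = 10,
                             planted_frac = 0, n_planted = 1, seed = 1)
  expect_length(lib0$sets[[1]], 10)
  expect_identical(
    serialize(simulate_gene_sets(truth, seed = 2), NULL),
    serialize(simulate_gene_sets(truth, seed = 2), NULL))
})

test_that("the marker fixture plants exactly the advertised contaminants", {
  fx <- simulate_marker_fixture(n_celltypes = 4, n_genes = 300,
                                n_contaminants = 4, seed = 8)
  out <- filter_ambient_degs(fx$degs[[fx$target]], fx$target, fx$markers,
                             fx$expr_ranks)
  expect_equal(sort(out$excluded$gene), fx$contaminants)
  expect_equal(length(out$excluded$gene), 4)
  # contaminants are top-5 foreign markers inside the expressed top 50
  for (g in fx$contaminants) {
    mk <- fx$markers[fx$markers$gene == g, ]
    expect_true(all(mk$cell_type != fx$target) && any(mk$rank <= 5))
    expect_lte(fx$expr_ranks$rank[fx$expr_ranks$gene == g], 50)
  }
})

test_that("synthetic study collections are written deterministically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- write_synthetic_study(d1, seed = 3, n_genes = 300, n_program = 40,
                              include_ci = FALSE, include_clock = TRUE)
  s2 <- write_synthetic_study(d2, seed = 3, n_genes = 300, n_program = 40,
                              include_ci = FALSE, include_clock = TRUE)
  f1 <- list.files(d1, recursive = TRUE)
  expect_equal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # the manifest round-trips into readable signature tables
  m <- read_manifest(file.path(d1, "manifest.tsv"))
  expect_gt(nrow(m), 10)
  tab <- read_signature_table(m$path[1], gerosig:::manifest_context(m[1, ]))
  expect_equal(nrow(tab), 300)
  expect_true(file.exists(s1$paths$gmt))
  expect_false(identical(
    readLines(file.path(d1, "signatures/ctx_01.tsv")),
    {
      d3 <- withr::local_tempdir()
      write_synthetic_study(d3, seed = 4, n_genes = 300, n_program = 40,
                            include_ci = FALSE, include_clock = FALSE)
      readLines(file.path(d3, "signatures/ctx_01.tsv"))
    }))
})
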