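# fixture: one intervention with three units; gene membership controlled
# per unit through the fdr column
conv_tables <- function(intervention = "senolysis", role = "GI",
                        units = c("liver", "lung", "kidney"),
                        deg_map = list()) {
  genes <- sprintf("g%02d", 1:20)
  lapply(units, function(u) {
    lfc <- rep(1, 20)
    fdr <- rep(0.9, 20)
    planted <- deg_map[[u]]
    if (!is.null(planted)) {
      idx <- match(names(planted), genes)
      lfc[idx] <- planted
      fdr[idx] <- 0.001
    }
    make_sig(genes, lfc, fdr = fdr, study = intervention, unit = u,
             role = role, intervention = intervention,
             modality = if (role %in% c("YPAR")) "single_cell" else "bulk")
  })
}

test_that("intervention sets honour the per-intervention context-count rules", {
  tabs <- conv_tables(deg_map = list(
    liver = c(g01 = 1, g02 = 1),
    lung = c(g02 = 1, g03 = -1),
    kidney = c(g02 = 1)))
  # senolysis rule: >= 1 organ suffices
  s1 <- intervention_deg_set(tabs, intervention_rule("senolysis", 1, "up"))
  expect_setequal(s1, c("g01", "g02"))
  # a >= 2 rule drops single-organ genes
  s2 <- intervention_deg_set(tabs, intervention_rule("senolysis", 2, "up"))
  expect_equal(s2, "g02")
  # >= 3 units
  s3 <- intervention_deg_set(tabs, intervention_rule("senolysis", 3, "up"))
  expect_equal(s3, "g02")
  # direction-specific: g03 is only a down-DEG
  expect_equal(intervention_deg_set(tabs, intervention_rule("senolysis", 1, "down")),
               "g03")
  # label mismatch errors
  expect_error(intervention_deg_set(tabs, intervention_rule("reprogramming", 2, "up")),
               "does not match")
})

test_that("raising min_contexts never grows an intervention set", {
  tabs <- conv_tables(deg_map = list(
    liver = c(g01 = 1, g02 = 1, g05 = 1),
    lung = c(g02 = 1, g05 = 1),
    kidney = c(g05 = 1)))
  sets <- lapply(1:3, function(m)
    intervention_deg_set(tabs, intervention_rule("senolysis", m, "up")))
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("trend intersection matches exhaustive per-gene enumeration", {
  genes <- sprintf("g%02d", 1:20)
  set.seed(9)
  gi_sets <- list(senolysis = sample(genes, 6), caloric_restriction = sample(genes, 5),
                  reprogramming = sample(genes, 4), parabiosis = sample(genes, 7))
  ypar <- sample(genes, 5)
  aging <- data.frame(gene = sample(genes, 8),
                      direction = sample(c("up", "down"), 8, replace = TRUE))
  mem <- trend_intersection(gi_sets, ypar, aging, trend = "gi_up")
  # oracle: loop every gene over every set
  aging_down <- aging$gene[aging$direction == "down"]
  all_sets <- c(gi_sets, list(ypar = ypar, aging = aging_down))
  for (g in genes) {
    inset <- vapply(all_sets, function(s) g %in% s, logical(1))
    row <- mem[mem$gene == g, ]
    if (sum(inset) == 0) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(row$n_sets, sum(inset))
      expect_equal(unlist(row[names(all_sets)]), inset,
                   ignore_attr = TRUE)
    }
  }
})

test_that("membership arithmetic follows the sharing example", {
  gi_sets <- list(senolysis = "gA", caloric_restriction = "gA",
                  reprogramming = character(0), parabiosis = character(0))
  aging <- data.frame(gene = c("gA", "gB"), direction = c("up", "up"))
  mem <- trend_intersection(gi_sets, character(0), aging, trend = "gi_down")
  expect_equal(mem$n_sets[mem$gene == "gA"], 3L)  # 2 GI sets + aging-up
  expect_equal(mem$n_sets[mem$gene == "gB"], 1L)  # retained below threshold
})

test_that("the shared-gene report filters, sorts and flags conflicts", {
  gi_sets <- list(a = c("g1", "g2"), b = c("g1", "g2"), c = "g1",
                  d = character(0))
  aging <- data.frame(gene = c("g1", "g3"), direction = c("up", "down"))
  mem_dn <- trend_intersection(gi_sets, character(0), aging, "gi_down")
  mem_up <- trend_intersection(list(a = "g3", b = "g3", c = character(0),
                                    d = character(0)),
                               "g2", aging, "gi_up")
  mem <- rbind(mem_up, mem_dn)
  rep3 <- shared_gene_report(mem, k = 3)
  expect_setequal(rep3$gene, c("g1", "g3"))
  expect_true(all(diff(match(rep3$trend, c("gi_down", "gi_up"))) >= 0))
  # g2 qualifies under both trends: flagged at k = 1, never merged
  rep1 <- shared_gene_report(mem, k = 1)
  expect_equal(sum(rep1$gene == "g2"), 2)
  expect_true(all(rep1$conflict[rep1$gene == "g2"]))
  expect_false(any(rep1$conflict[rep1$gene != "g2"]))
  # raising k never grows the report; k above the maximum empties it
  expect_lte(nrow(rep3), nrow(rep1))
  expect_equal(nrow(shared_gene_report(mem, k = 6)), 0)
  # fold-change matrix columns are NA where the gene is untested
  tab <- make_sig(c("g1", "g9"), c(0.5, 1))
  repfc <- shared_gene_report(mem_dn, tables = list(tab), k = 1)
  expect_equal(repfc[["log2fc.s1|g|liver"]][repfc$gene == "g1"], 0.5)
  expect_true(is.na(repfc[["log2fc.s1|g|liver"]][repfc$gene == "g2"]))
})

test_that("Venn region counts partition the retained genes", {
  set.seed(21)
  genes <- sprintf("g%02d", 1:20)
  gi_sets <- list(a = sample(genes, 8), b = sample(genes, 8),
                  c = sample(genes, 8), d = sample(genes, 8))
  aging <- data.frame(gene = sample(genes, 10),
                      direction = sample(c("up", "down"), 10, replace = TRUE))
  mem <- trend_intersection(gi_sets, sample(genes, 5), aging, "gi_down")
  venn <- venn_region_counts(mem)
  expect_equal(sum(venn$count), nrow(mem))
  expect_true(all(venn$n_sets >= 1))
})

test_that("direction consistency is the majority fraction among DEG calls", {
  mk <- function(lfc, unit) make_sig("gX", lfc, fdr = 0.001, unit = unit)
  up3dn1 <- list(mk(1, "a"), mk(1, "b"), mk(1, "c"), mk(-1, "d"))
  expect_equal(direction_consistency("gX", up3dn1), 0.75)
  expect_equal(direction_consistency("gX", up3dn1[1:3]), 1.0)
  expect_equal(direction_consistency("gX", list(mk(1, "a"), mk(1, "b"),
                                                mk(-1, "c"), mk(-1, "d"))), 0.5)
  none <- make_sig("gX", 0.01, fdr = 0.9)
  expect_error(direction_consistency("gX", list(none)), "not a DEG")
})
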