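test_that("the expression prefilter applies both strict criteria", {
  ncell <- 1000
  counts <- rbind(
    sparse_low = c(rep(2, 5), rep(0, ncell - 5)),        # 0.5% of cells
    good = c(rep(2, 20), rep(0, ncell - 20)),            # 2%, 20 cells > 1 UMI
    boundary_frac = c(rep(2, 10), rep(0, ncell - 10)),   # exactly 1%: fails
    boundary_cells = c(rep(2, 12), rep(0, ncell - 12)),  # 1.2% but check UMI rule
    shallow = c(rep(1, 100), rep(0, ncell - 100)),       # 10% but never > 1 UMI
    zero = rep(0, ncell))
  colnames(counts) <- sprintf("c%04d", seq_len(ncell))
  kept <- prefilter_genes(counts)
  expect_true(all(c("good", "boundary_cells") %in% kept))
  expect_false("sparse_low" %in% kept)
  expect_false("boundary_frac" %in% kept)   # > is strict
  expect_false("shallow" %in% kept)         # needs > 1 UMI in > 5 cells
  expect_false("zero" %in% kept)
  # exactly 5 cells above 1 UMI fails the strict bound; 6 passes
  m <- rbind(five = c(rep(3, 5), rep(1, 50), rep(0, 145)),
             six = c(rep(3, 6), rep(1, 50), rep(0, 144)))
  colnames(m) <- sprintf("c%03d", 1:200)
  expect_equal(prefilter_genes(m), "six")
  expect_error(prefilter_genes(counts[, 0, drop = FALSE]), ">= 1 cell")
})

test_that("expression ranking normalizes by library size and breaks ties lexically", {
  counts <- matrix(c(100, 10, 10,
                     100, 10, 10), nrow = 3,
                   dimnames = list(c("big", "tie_b", "tie_a"), c("c1", "c2")))
  er <- rank_expression(counts)
  expect_equal(er$gene, c("big", "tie_a", "tie_b"))
  expect_equal(er$rank, 1:3)
  # normalization: a gene dominant in a shallow cell outranks raw totals
  counts2 <- matrix(c(0, 8,
                      90, 10), nrow = 2, byrow = TRUE,
                    dimnames = list(c("shallow_hero", "deep"), c("c1", "c2")))
  # totals: raw 8 vs 100, but normalized 0/90 + 8/18 vs 90/90 + 10/18
  er2 <- rank_expression(counts2)
  expect_equal(er2$gene[1], "deep")
  er2_raw <- rank_expression(counts2, normalize = FALSE)
  expect_equal(er2_raw$total[er2_raw$gene == "deep"], 100)
})

test_that("MTX and dense count inputs are equivalent", {
  skip_if_not_installed("Matrix")
  m <- matrix(rpois(60, 3), 6, 10,
              dimnames = list(sprintf("g%d", 1:6), sprintf("c%02d", 1:10)))
  dense_path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
              dense_path, sep = "\t", quote = FALSE, row.names = FALSE)
  mtx_path <- withr::local_tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx_path)
  writeLines(rownames(m), paste0(mtx_path, ".genes"))
  writeLines(colnames(m), paste0(mtx_path, ".cells"))
  dense <- read_counts(dense_path)
  sparse <- read_counts(mtx_path)
  expect_equal(as.matrix(sparse), dense, ignore_attr = TRUE)
  expect_equal(rank_expression(dense), rank_expression(sparse))
})

ambient_fixture <- function() {
  markers <- marker_table(data.frame(
    cell_type = rep(c("A", "B"), each = 6),
    gene = c(sprintf("am%d", 1:6), sprintf("bm%d", 1:6)),
    rank = rep(1:6, 2),
    statistic = rep(seq(3, 1, length.out = 6), 2)))
  # bm2 highly expressed; bm6 is rank 6 (outside top 5); am1 is A's own
  expr_ranks <- data.frame(
    gene = c("bm2", "bm6", "other1", "am1", sprintf("x%02d", 1:60),
             "bm3", sprintf("clean%d", 1:3)),
    rank = 1:68)
  list(markers = markers, expr_ranks = expr_ranks)
}

test_that("ambient exclusion needs both criteria and spares own markers", {
  fx <- ambient_fixture()
  degs <- c("bm2", "bm3", "am1", "clean1")
  out <- filter_ambient_degs(degs, "A", fx$markers, fx$expr_ranks)
  # bm2: rank-2 marker of B and rank-1 expressed -> excluded with reasons
  expect_equal(out$excluded$gene, "bm2")
  expect_equal(out$excluded$offending_cell_type, "B")
  expect_equal(out$excluded$marker_rank, 2L)
  expect_equal(out$excluded$expression_rank, 1L)
  # bm3: foreign top-5 marker but rank 65 expressed -> retained
  # am1: own marker, highly expressed -> retained
  expect_setequal(out$retained, c("bm3", "am1", "clean1"))
  # partition property
  expect_setequal(c(out$retained, out$excluded$gene), degs)
  # inclusive rank bounds: a rank-5 marker at expression rank 50 is excluded
  fx$expr_ranks$rank[fx$expr_ranks$gene == "bm3"] <- 50L
  out2 <- filter_ambient_degs(c("bm5", "bm3"), "A", fx$markers, fx$expr_ranks,
                              top_markers = 5, top_expressed = 50)
  expect_true("bm3" %in% out2$excluded$gene)
  expect_error(filter_ambient_degs(degs, "Z", fx$markers, fx$expr_ranks),
               "absent from")
})

test_that("exclusion is monotone in both rank thresholds", {
  fx <- ambient_fixture()
  degs <- c("bm2", "bm3", "bm6", "am1", "clean1")
  base <- filter_ambient_degs(degs, "A", fx$markers, fx$expr_ranks,
                              top_markers = 5, top_expressed = 50)
  wider_m <- filter_ambient_degs(degs, "A", fx$markers, fx$expr_ranks,
                                 top_markers = 6, top_expressed = 50)
  wider_e <- filter_ambient_degs(degs, "A", fx$markers, fx$expr_ranks,
                                 top_markers = 5, top_expressed = 70)
  expect_true(all(base$excluded$gene %in% wider_m$excluded$gene))
  expect_true(all(base$excluded$gene %in% wider_e$excluded$gene))
  # bm6 becomes an offender only once rank 6 markers count
  expect_true("bm6" %in% wider_m$excluded$gene)
  expect_false("bm6" %in% base$excluded$gene)
})

test_that("the planted fixture is recovered exactly", {
  fx <- simulate_marker_fixture(n_celltypes = 3, n_genes = 200, seed = 4)
  out <- filter_ambient_degs(fx$degs[[fx$target]], fx$target, fx$markers,
                             fx$expr_ranks)
  expect_setequal(out$excluded$gene, fx$contaminants)
  # clean DEG lists of other cell types are never touched
  for (ct in setdiff(fx$cell_types, fx$target)) {
    o <- filter_ambient_degs(fx$degs[[ct]], ct, fx$markers, fx$expr_ranks)
    expect_equal(nrow(o$excluded), 0)
  }
  # the counts matrix reproduces the planted expression ranking
  er <- rank_expression(fx$counts)
  expect_equal(er$gene, fx$expr_ranks$gene)
  expect_equal(er$gene[1], fx$expr_ranks$gene[1])
})
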