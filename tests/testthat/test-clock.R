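toy_expr <- function(counts, lengths = NULL, units = "counts",
                     groups = NULL) {
  expression_matrix(counts, lengths = lengths, groups = groups, units = units)
}

test_that("homolog mapping renames, drops and resolves collisions", {
  counts <- matrix(1:8, 4, 2,
                   dimnames = list(c("Cat", "Sod1", "Gpx1", "Unknown"),
                                   c("s1", "s2")))
  lens <- c(Cat = 1000, Sod1 = 2000, Gpx1 = 1500, Unknown = 800)
  map <- data.frame(source = c("Cat", "Sod1", "Gpx1"),
                    target = c("CAT", "SOD1", "SOD1"))
  ex <- toy_expr(counts, lens)
  mapped <- map_homologs(ex, map, collision_policy = "sum")
  expect_setequal(rownames(mapped$counts), c("CAT", "SOD1"))
  # direct mapping renames the row
  expect_equal(mapped$counts["CAT", ], counts["Cat", ])
  # sum policy conserves total mapped abundance
  expect_equal(sum(mapped$counts), sum(counts[1:3, ]))
  expect_equal(mapped$counts["SOD1", ], counts["Sod1", ] + counts["Gpx1", ])
  # unmapped genes are dropped and counted
  expect_equal(attr(mapped, "n_unmapped"), 1L)
  # collided target takes the longest source length
  expect_equal(unname(mapped$lengths["SOD1"]), 2000)
  # max policy keeps the dominant row
  mx <- map_homologs(ex, map, collision_policy = "max")
  expect_equal(unname(mx$counts["SOD1", ]), unname(counts["Gpx1", ]))
  expect_error(map_homologs(ex, map, collision_policy = "error"), "SOD1")
  # one-to-many source symbols use the first listed target
  map2 <- data.frame(source = c("Cat", "Cat"), target = c("CAT", "CAT2"))
  m2 <- map_homologs(ex, map2)
  expect_true("CAT" %in% rownames(m2$counts))
  expect_false("CAT2" %in% rownames(m2$counts))
  expect_equal(attr(m2, "n_one_to_many"), 1L)
})

test_that("normalization applies the length, depth and UMI conventions", {
  counts <- matrix(c(100, 100, 300), 3, 1,
                   dimnames = list(c("short", "long", "rest"), "s1"))
  lens <- c(short = 1000, long = 10000, rest = 2000)
  tr <- normalize_for_clock(toy_expr(counts, lens))
  # equal counts, 10x length ratio -> 10x abundance ratio
  ab <- 2^tr - 1
  expect_equal(unname(ab["short", 1] / ab["long", 1]), 10)
  # UMI units force every effective length to 10,000 bases: the result is
  # identical to stating 10 kb lengths explicitly
  umi <- normalize_for_clock(toy_expr(counts, units = "UMI"))
  explicit <- normalize_for_clock(
    toy_expr(counts, lengths = setNames(rep(10000, 3), rownames(counts))))
  expect_equal(umi, explicit, ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(unname(umi), unname(tr))))
  # all-zero sample: transform of zero everywhere
  z <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_true(all(normalize_for_clock(toy_expr(z, c(a = 1, b = 1))) == 0))
  expect_error(normalize_for_clock(toy_expr(counts)), "lengths required")
})

test_that("clock evaluation is linear with zero-imputed missing genes", {
  clock <- clock_model(50, c(gA = 2, gB = -1))
  # a present clock gene at the transform of zero leaves the intercept
  t0 <- matrix(0, 2, 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_equal(as.numeric(apply_clock(t0, clock)), c(50, 50))
  # doubling a positive-coefficient gene raises age by coef x delta
  t1 <- t0; t1["gA", "s2"] <- 3
  ages <- apply_clock(t1, clock)
  expect_equal(as.numeric(ages["s2"] - ages["s1"]), 2 * 3)
  # linearity: age(a x + b y) = a age(x) + b age(y) - (a + b - 1) intercept
  x <- matrix(rnorm(2), 2, 1, dimnames = list(c("gA", "gB"), "s"))
  y <- matrix(rnorm(2), 2, 1, dimnames = list(c("gA", "gB"), "s"))
  a <- 0.3; b <- 1.4
  lhs <- apply_clock(a * x + b * y, clock)
  rhs <- a * apply_clock(x, clock) + b * apply_clock(y, clock) -
    (a + b - 1) * 50
  expect_equal(as.numeric(lhs), as.numeric(rhs))
  # missing clock genes impute to transform-of-zero and are counted
  tA <- matrix(1, 1, 1, dimnames = list("gA", "s1"))
  out <- apply_clock(tA, clock)
  expect_equal(as.numeric(out), 50 + 2 * 1)
  expect_equal(attr(out, "n_imputed"), 1L)
  none <- matrix(1, 1, 1, dimnames = list("gZ", "s1"))
  expect_error(apply_clock(none, clock), "no clock gene")
})

test_that("planted clock expression is recovered exactly without noise", {
  clock <- make_synthetic_clock(n_genes = 25, intercept = 50, seed = 2)
  ages <- c(40, 55, 62.5, 70, 80)
  expr <- simulate_clock_expression(clock, ages, noise_sd = 0, seed = 3)
  est <- apply_clock(normalize_for_clock(expr,
                                         clock$transform$pseudocount), clock)
  expect_equal(as.numeric(est), ages, tolerance = 1e-6)
  # equal target ages give a constant readout
  flat <- simulate_clock_expression(clock, rep(50, 4), noise_sd = 0, seed = 3)
  est_flat <- apply_clock(normalize_for_clock(flat), clock)
  expect_equal(max(est_flat) - min(est_flat), 0, tolerance = 1e-9)
})

test_that("recovery error grows with transformed-expression noise", {
  clock <- make_synthetic_clock(n_genes = 25, intercept = 50, seed = 2)
  ages <- seq(40, 80, length.out = 6)
  err_at <- function(noise, seed) {
    expr <- simulate_clock_expression(clock, ages, noise_sd = noise,
                                      seed = seed)
    est <- apply_clock(normalize_for_clock(expr), clock)
    sqrt(mean((est - ages)^2))
  }
  mean_err <- vapply(c(0.05, 0.3, 1.0), function(ns)
    mean(vapply(1:15, function(s) err_at(ns, s), numeric(1))), numeric(1))
  expect_true(all(diff(mean_err) > 0))
})

test_that("age scaling follows the stated conventions per panel", {
  expect_equal(as.numeric(scale_ages(c(40, 60), method = "zscore")), c(-1, 1))
  expect_equal(as.numeric(scale_ages(c(40, 50, 60), method = "minmax")),
               c(0, 0.5, 1))
  ages <- c(a = 40, b = 60, c = 10, d = 30)
  expect_equal(scale_ages(ages, method = "none"), ages, ignore_attr = TRUE)
  # panel-wise: each panel scaled independently
  sc <- scale_ages(ages, method = "zscore", panels = c("p1", "p1", "p2", "p2"))
  expect_equal(as.numeric(sc), c(-1, 1, -1, 1))
  expect_warning(out <- scale_ages(c(5, 5), method = "minmax"), "constant")
  expect_equal(as.numeric(out), c(0, 0))
})

test_that("group comparison uses the exact rank-sum distribution", {
  r <- compare_groups(c(1, 2, 3, 4), factor(c("a", "a", "b", "b"),
                                            levels = c("a", "b")))
  expect_equal(r$delta, 2)
  # exact enumeration of the 6 assignments: both extremes, two-sided
  expect_equal(r$pvalue, ranksum_oracle(c(1, 2), c(3, 4)), tolerance = 1e-12)
  expect_equal(r$pvalue, 1 / 3, tolerance = 1e-12)
  same <- compare_groups(c(1, 2, 1, 2), factor(c("a", "a", "b", "b")))
  expect_equal(same$delta, 0)
  expect_equal(same$pvalue, 1)
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(5)
    r <- compare_groups(c(x, y), rep(c("a", "b"), c(4, 5)))
    expect_equal(r$pvalue, ranksum_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), ">= 2 samples")
})

test_that("clock models round-trip through their file format", {
  clock <- clock_model(17.25, c(CAT = 1.5, SOD1 = -0.75, GPX1 = 0),
                       pseudocount = 0.5, tissue = "liver")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clock_model(clock, path)
  back <- read_clock_model(path)
  expect_equal(back$intercept, clock$intercept)
  expect_equal(back$coefficients, clock$coefficients)
  expect_equal(back$transform, clock$transform)
  expect_equal(back$tissue, "liver")
  expect_error(clock_model(10, c(a = 0, b = 0)), "nonzero")
})
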