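# Brute-force oracles, independent of the package's implementation paths,
# plus small fixture builders.

# step-up BH by direct definition: adj_(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- sorted * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# recursive permutation generator (distinct from the package's iterative
# insertion builder)
perms_rec <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# exhaustive two-sided permutation p-value for Spearman's rho via
# stats::cor on every permutation
perm_pvalue_oracle <- function(x, y) {
  rho_obs <- stats::cor(x, y, method = "spearman")
  rhos <- vapply(perms_rec(seq_along(y)), function(p)
    stats::cor(x, y[p], method = "spearman"), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# upper hypergeometric tail by direct summation of the pmf
hyper_tail_oracle <- function(k, set_size, bg_size, list_size) {
  j <- k:min(set_size, list_size)
  sum(choose(set_size, j) * choose(bg_size - set_size, list_size - j)) /
    choose(bg_size, list_size)
}

# exact two-sided rank-sum p-value by enumerating all group assignments
ranksum_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(pooled)
  obs <- sum(r[(length(x) + 1):n])
  combos <- utils::combn(n, length(y))
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

make_sig <- function(genes, lfc, fdr = rep(1e-4, length(genes)),
                     pvalue = fdr, study = "s1", group = "g",
                     unit = "liver", modality = "bulk", role = "GI",
                     intervention = "") {
  signature_table(genes, lfc, pvalue, fdr = fdr,
                  context = context_key(study, group, unit, modality, role,
                                        intervention))
}

# random signature table: n genes, a fraction of clear DEGs
random_sig <- function(n = 50, seed = 1, ...) {
  stats <- local({
    set.seed(seed)
    lfc <- rnorm(n, 0, 1)
    p <- runif(n)^2
    list(lfc = lfc, p = p)
  })
  make_sig(sprintf("g%03d", seq_len(n)), stats$lfc, fdr = stats$p,
           pvalue = stats$p, ...)
}

# one synthetic study collection in memory: ground truth plus signature
# tables for every design context
simulate_collection <- function(seed, noise_sd = 0.2, include_ci = FALSE) {
  truth <- generate_ground_truth(noise_sd = noise_sd, seed = seed)
  design <- gerosig:::default_study_design(include_ci = include_ci)
  tables <- lapply(seq_len(nrow(design)), function(i)
    simulate_signature(truth, gerosig:::manifest_context(design[i, ]),
                       seed = gerosig:::derive_seed(seed, i)))
  list(truth = truth, design = design, tables = tables)
}

# direction-specific intervention/Y-Par sets at the default context rules
build_trend_memberships <- function(col) {
  design <- col$design; tables <- col$tables
  thr <- deg_thresholds()
  rules <- list(senolysis = 1, caloric_restriction = 2, reprogramming = 2,
                parabiosis = 3)
  build <- function(direction) {
    sets <- list()
    for (iv in names(rules)) {
      idx <- which(design$role == "GI" & design$intervention == iv)
      sets[[iv]] <- intervention_deg_set(
        tables[idx], intervention_rule(iv, rules[[iv]], direction), thr)
    }
    sets
  }
  ypar <- function(direction) {
    idx <- which(design$role == "YPAR")
    intervention_deg_set(tables[idx],
                         intervention_rule("parabiosis", 3, direction), thr)
  }
  aging <- truth_aging_list(col$truth)
  rbind(trend_intersection(build("up"), ypar("down"), aging, "gi_up"),
        trend_intersection(build("down"), ypar("up"), aging, "gi_down"))
}
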