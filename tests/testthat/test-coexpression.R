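expr_fixture <- function(n_genes = 20, n_samples = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  m
}

test_that("similarity is unsigned with unit diagonal", {
  x <- rnorm(30)
  e <- rbind(g1 = x, g2 = -x, g3 = x + rnorm(30, sd = 0.2))
  colnames(e) <- sprintf("s%d", 1:30)
  s <- similarity_matrix(e)
  expect_equal(unname(s["g1", "g2"]), 1)
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_true(all(s >= 0 & s <= 1))

  set.seed(5)
  noise <- matrix(rnorm(5 * 2000), 5, 2000)
  rownames(noise) <- sprintf("g%d", 1:5)
  s2 <- similarity_matrix(noise)
  expect_lt(max(s2[upper.tri(s2)]), 0.1)

  e_const <- rbind(e, g4 = rep(2, 30))
  expect_warning(s3 <- similarity_matrix(e_const), "constant")
  expect_equal(nrow(s3), 3)
  expect_error(similarity_matrix(e[, 1:2]), "3 samples")
})

test_that("soft-threshold adjacency is an elementwise power", {
  e <- expr_fixture()
  s <- similarity_matrix(e)
  expect_equal(unclass(adjacency_matrix(s, 1)), unclass(s),
               ignore_attr = TRUE)
  s_fixed <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  a <- adjacency_matrix(s_fixed, 12)
  expect_equal(a[1, 2], 0.2824295, tolerance = 1e-6)
  expect_equal(a[1, 1], 1)
  expect_error(adjacency_matrix(s, 0.5), "beta")
  # monotonicity: larger beta never increases any entry
  for (b in c(2, 4, 8)) {
    expect_true(all(adjacency_matrix(s, b + 1) <= adjacency_matrix(s, b)))
  }
})

test_that("scale-free fit separates power-law from Poisson graphs", {
  pa <- simulate_graph("preferential_attachment", 500, m = 2, seed = 2)
  er <- simulate_graph("erdos_renyi", 500, p = 0.05, seed = 2)
  fit_pa <- scale_free_fit(pa)
  fit_er <- scale_free_fit(er)
  expect_gt(fit_pa, 0.8)
  expect_lt(fit_er, fit_pa)
  expect_error(scale_free_fit(simulate_graph("complete", 10)), "undefined")
})

test_that("soft-threshold selection returns the smallest adequate power", {
  e <- expr_fixture(50, 12, seed = 3)
  single <- pick_soft_threshold(e, powers = 7)
  expect_equal(single$beta, 7)
  expect_equal(nrow(single$fit_table), 1)

  pick <- pick_soft_threshold(e, powers = 1:10)
  expect_equal(nrow(pick$fit_table), 10)
  expect_true(pick$beta %in% 1:10)

  trivial <- pick_soft_threshold(e, powers = 3:10, target_fit = -1)
  expect_equal(trivial$beta, 3)
})

test_that("topological overlap matches hand-computed cases", {
  clique <- matrix(1, 5, 5)
  tom <- topological_overlap(clique)
  expect_true(all(abs(tom - 1) < 1e-12))

  pair <- diag(4)
  pair[1, 2] <- pair[2, 1] <- 1
  tom2 <- topological_overlap(pair)
  expect_equal(tom2[1, 2], 1)  # (0 + 1) / (1 + 1 - 1)
  expect_equal(tom2[3, 4], 0)  # no edge, no shared neighbours

  set.seed(9)
  for (i in 1:100) {
    a <- rand_adjacency(sample(4:12, 1))
    tom <- topological_overlap(a)
    expect_true(isSymmetric(unname(tom), tol = 1e-10))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(unname(diag(tom)), rep(1, nrow(a)))
  }
})

test_that("average-linkage tree follows hand-computed merge heights", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- cluster_gene_tree(d)
  expect_equal(tree$height, c(0.1, 0.9))

  same <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(cluster_gene_tree(same)$height, 0)

  lone <- matrix(0, 1, 1, dimnames = list("a", "a"))
  tree1 <- cluster_gene_tree(lone)
  expect_equal(nrow(tree1$merge), 0)

  d_bad <- d
  d_bad[1, 2] <- NaN
  expect_error(cluster_gene_tree(d_bad), "finite")
})

test_that("module cutting handles degenerate trees", {
  n <- 40
  d <- matrix(1e-6, n, n)
  diag(d) <- 0
  dimnames(d) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
  mods <- cut_modules(cluster_gene_tree(d), min_module_size = 30)
  expect_true(all(mods$module == 1))  # one module containing all genes

  mods2 <- cut_modules(cluster_gene_tree(d), min_module_size = n + 1)
  expect_true(all(mods2$module == 0))  # nothing reaches the minimum size
  expect_true(all(mods2$color == "grey"))
})

test_that("eigengenes summarize modules deterministically", {
  x <- rnorm(12)
  e <- rbind(g1 = x, g2 = x, g3 = x, g4 = -x + rnorm(12, sd = 0.01))
  colnames(e) <- sprintf("s%d", 1:12)
  mods <- stats::setNames(c(1, 1, 1, 1), rownames(e))
  me <- module_eigengenes(e, mods)
  expect_equal(attr(me, "var_explained")[["ME1"]], 1, tolerance = 0.01)
  # sign convention: positively correlated with the module mean profile
  expect_gt(stats::cor(me[, "ME1"], colMeans(t(scale(t(e))))), 0)

  # two perfectly anticorrelated genes span one dimension after
  # standardization, so the first component carries all the variance and
  # the output is deterministic
  e2 <- rbind(g1 = x, g2 = -x)
  colnames(e2) <- colnames(e)
  me2 <- module_eigengenes(e2, stats::setNames(c(1, 1), rownames(e2)))
  expect_equal(attr(me2, "var_explained")[["ME1"]], 1, tolerance = 1e-8)
  me2b <- module_eigengenes(e2[c("g2", "g1"), ],
                            stats::setNames(c(1, 1), c("g2", "g1")))
  expect_equal(me2b[, "ME1"], me2[, "ME1"])

  # permuting gene order leaves the eigengene unchanged
  perm <- c("g3", "g1", "g4", "g2")
  me3 <- module_eigengenes(e[perm, ], mods[perm])
  expect_equal(me3[, "ME1"], me[, "ME1"])
})

test_that("module merging joins duplicates and is idempotent", {
  x <- rnorm(10)
  e <- rbind(g1 = x, g2 = x + rnorm(10, 0.01), g3 = x + rnorm(10, 0.01),
             g4 = x, g5 = x + rnorm(10, 0.01), g6 = x + rnorm(10, 0.01))
  colnames(e) <- sprintf("s%d", 1:10)
  mods <- stats::setNames(c(1, 1, 1, 2, 2, 2), rownames(e))
  merged <- merge_close_modules(e, mods, cut = 0.25)
  expect_equal(max(merged$module), 1)  # identical eigengenes merge

  y <- matrix(rnorm(60), 6, 10,
              dimnames = list(rownames(e), colnames(e)))
  no_merge <- merge_close_modules(y, mods, cut = 0)
  expect_equal(max(no_merge$module), 2)  # cut 0 never merges

  again <- merge_close_modules(e[merged$gene_id, ], merged, cut = 0.25)
  expect_equal(again$module, merged$module)
})

test_that("planted modules are recovered through the full stage", {
  cfg <- sim_config(n_genes = 500, n_modules = 4, module_size = 50,
                    n_samples = 20, within_module_cor = 0.7,
                    de_gene_frac = 0, n_rule_groups = 0, rule_group_size = 0,
                    nb_dispersion = 0.02, baseline_log_mean = log(500),
                    seed = 5)
  sim <- simulate_counts(cfg)
  expr <- log2_expression(sim$counts)
  beta <- pick_soft_threshold(expr)$beta
  tom <- topological_overlap(adjacency_matrix(similarity_matrix(expr), beta))
  mods <- cut_modules(cluster_gene_tree(1 - tom), 30)
  mods <- merge_close_modules(expr[mods$gene_id, ], mods, 0.25)
  mods <- assign_by_membership(expr[mods$gene_id, ], mods, 0.6)
  ari <- mclust::adjustedRandIndex(sim$truth$module_of_gene[mods$gene_id],
                                   mods$module)
  expect_gt(ari, 0.75)
})
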