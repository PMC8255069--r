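graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

test_that("network construction thresholds edges correctly", {
  w <- matrix(c(1, 0.8, 0.4,
                0.8, 1, 0.2,
                0.4, 0.2, 1), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net <- build_network(w, edge_threshold = 0.5)
  expect_equal(igraph::ecount(net), 1)
  el <- igraph::as_edgelist(net)
  expect_setequal(as.vector(el), c("a", "b"))
  expect_equal(igraph::E(net)$weight, 0.8)

  expect_equal(igraph::ecount(build_network(w, 0.99)), 0)
  expect_equal(igraph::ecount(build_network(w, 0.1)), 3)
  expect_error(build_network(w, 0), "edge_threshold")
  expect_error(build_network(w, 1), "edge_threshold")

  cats <- data.frame(gene_id = c("a", "b"),
                     category = c("chemosensory", "non_chemosensory"))
  net2 <- build_network(w, 0.5, categories = cats)
  expect_equal(igraph::V(net2)$category,
               c("chemosensory", "non_chemosensory", "unannotated"))
})

test_that("centralities match closed forms on canonical graphs", {
  path3 <- simulate_graph("path", 3)
  ct <- centrality_table(path3)
  expect_equal(ct$betweenness, c(0, 1, 0))
  expect_equal(ct$closeness, c(2 / 3, 1, 2 / 3))

  star <- simulate_graph("star", 5)
  ct_star <- centrality_table(star)
  expect_equal(ct_star$degree, c(4, 1, 1, 1, 1))
  expect_equal(ct_star$clustering_coefficient[1], 0)

  k4 <- simulate_graph("complete", 4)
  ct_k4 <- centrality_table(k4)
  expect_equal(ct_k4$betweenness, rep(0, 4))
  expect_equal(ct_k4$closeness, rep(1, 4))
  expect_equal(ct_k4$clustering_coefficient, rep(1, 4))

  # square with one diagonal: node 2's two neighbours are connected
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- A[4, 1] <- A[1, 3] <- 1
  A <- A + t(A)
  ct_sq <- centrality_table(graph_from_adj(A))
  expect_equal(ct_sq$clustering_coefficient[2], 1)

  iso <- igraph::make_empty_graph(3, directed = FALSE)
  ct_iso <- centrality_table(iso)
  expect_equal(ct_iso$degree, rep(0, 3))
  expect_equal(ct_iso$closeness, rep(0, 3))
})

test_that("centralities agree with brute-force path enumeration", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(8:25, 1)
    A <- matrix(rbinom(n * n, 1, 0.15), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    g <- graph_from_adj(A)
    ct <- centrality_table(g)
    expect_equal(ct$betweenness, bf_betweenness(A), tolerance = 1e-10)
    expect_equal(ct$closeness, bf_closeness(A), tolerance = 1e-10)
    expect_equal(ct$clustering_coefficient, bf_clustering(A),
                 tolerance = 1e-10)
    expect_equal(sum(ct$degree), 2 * igraph::ecount(g))  # handshake lemma
  }
})

test_that("density follows 2E / n(n-1)", {
  g <- withr::with_seed(1, igraph::sample_gnm(51, 148))
  expect_equal(round(graph_density(g), 3), 0.116)
  expect_equal(graph_density(simulate_graph("complete", 7)), 1)
  expect_equal(graph_density(igraph::make_empty_graph(10, directed = FALSE)),
               0)
  expect_error(graph_density(igraph::make_empty_graph(1, directed = FALSE)),
               "2 nodes")
})

test_that("degree filtering is single-pass by default", {
  star <- simulate_graph("star", 5)
  f <- filter_by_degree(star, 2)
  expect_equal(igraph::vcount(f), 1)  # centre survives the single pass
  expect_equal(igraph::ecount(f), 0)

  k6 <- simulate_graph("complete", 6)
  expect_equal(igraph::vcount(filter_by_degree(k6, 5)), 6)
  g <- simulate_graph("erdos_renyi", 30, p = 0.1, seed = 2)
  expect_equal(igraph::vcount(filter_by_degree(g, 0)), 30)

  # iterative mode is a k-core: every survivor keeps the degree bound
  g2 <- filter_by_degree(g, 2, iterative = TRUE)
  if (igraph::vcount(g2) > 0) {
    expect_true(all(igraph::degree(g2) >= 2))
  }
})

test_that("hub-core filtering increases density on core-periphery graphs", {
  set.seed(12)
  core <- matrix(rbinom(15 * 15, 1, 0.8), 15, 15)
  full <- matrix(0, 60, 60)
  full[1:15, 1:15] <- core
  for (v in 16:60) full[v, sample(1:15, 1)] <- 1  # sparse periphery
  full[lower.tri(full, diag = TRUE)] <- 0
  full <- full + t(full)
  g <- graph_from_adj(full)
  gf <- filter_by_degree(g, 5)
  expect_gt(graph_density(gf), graph_density(g))
})

test_that("hub table ranks by degree, betweenness, then id", {
  ct <- data.frame(gene = c("b", "a", "c", "d"),
                   degree = c(9, 9, 10, 2),
                   betweenness = c(0.5, 0.5, 0.1, 0.9),
                   closeness = rep(0.5, 4),
                   clustering_coefficient = rep(0.3, 4))
  hubs <- hub_table(ct, min_degree = 8)
  expect_equal(hubs$gene, c("c", "a", "b"))
  expect_equal(nrow(hub_table(ct, min_degree = 11)), 0)

  star <- simulate_graph("star", 6)
  ct_star <- centrality_table(star)
  expect_equal(hub_table(ct_star, min_degree = 5)$degree, 5)
})
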