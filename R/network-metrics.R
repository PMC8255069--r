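#' Build a gene network from a weight matrix
#'
#' Thresholds a symmetric gene x gene weight matrix (TOM or adjacency):
#' an edge joins genes i and j when `w_ij >= edge_threshold`. Weights are
#' kept as the `weight` edge attribute; optional gene categories
#' (chemosensory / non_chemosensory / unannotated) become the `category`
#' node attribute.
#'
#' @param weights symmetric matrix with values in `[0, 1]` and gene ids as
#'   dimnames.
#' @param edge_threshold weight cutoff in (0, 1).
#' @param node_subset optional character vector restricting the network to
#'   these genes.
#' @param categories optional named character vector (or data frame with
#'   `gene_id` and `category`) of node categories.
#' @return an undirected simple [igraph::igraph].
#' @export
build_network <- function(weights, edge_threshold = 0.2, node_subset = NULL,
                          categories = NULL) {
  if (edge_threshold <= 0 || edge_threshold >= 1) {
    stop("edge_threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  w <- as.matrix(weights)
  if (is.null(rownames(w))) {
    dimnames(w) <- list(sprintf("gene_%d", seq_len(nrow(w))),
                        sprintf("gene_%d", seq_len(ncol(w))))
  }
  if (!is.null(node_subset)) {
    keep <- intersect(rownames(w), node_subset)
    w <- w[keep, keep, drop = FALSE]
  }
  diag(w) <- 0
  w[w < edge_threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(categories)) {
    if (is.data.frame(categories)) {
      categories <- stats::setNames(categories$category, categories$gene_id)
    }
    cat_v <- unname(categories[igraph::V(g)$name])
    cat_v[is.na(cat_v)] <- "unannotated"
    igraph::V(g)$category <- cat_v
  }
  g
}

#' Per-node centrality measures
#'
#' Computes the four centralities used to rank hub genes: degree,
#' betweenness (fraction of unweighted shortest paths through the node,
#' normalized by `(n-1)(n-2)/2`), closeness (`(reachable - 1) / sum of
#' shortest distances`, per connected component; 0 for isolated nodes), and
#' the local clustering coefficient (edge density among neighbours; 0 for
#' degree < 2). Shortest paths are unweighted hop counts by default; set
#' `weighted = TRUE` to use `1/weight` as edge length instead.
#'
#' @param net an [igraph::igraph] from [build_network()].
#' @param weighted use edge weights for shortest-path measures.
#' @return data frame with `gene`, `degree`, `betweenness`, `closeness`,
#'   `clustering_coefficient`.
#' @export
centrality_table <- function(net, weighted = FALSE) {
  n <- igraph::vcount(net)
  w <- if (weighted) 1 / igraph::E(net)$weight else NA
  btw <- if (n < 3) {
    rep(0, n)
  } else {
    igraph::betweenness(net, directed = FALSE, weights = w,
                        normalized = TRUE)
  }
  cls <- suppressWarnings(
    igraph::closeness(net, weights = w, normalized = TRUE, mode = "all"))
  cls[!is.finite(cls)] <- 0
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  nm <- igraph::V(net)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  data.frame(gene = nm,
             degree = unname(igraph::degree(net)),
             betweenness = unname(btw),
             closeness = unname(cls),
             clustering_coefficient = unname(cc),
             stringsAsFactors = FALSE)
}

#' Network density
#'
#' Fraction of realizable edges present: `2|E| / (n(n-1))`.
#'
#' @param net an undirected [igraph::igraph] with at least 2 nodes.
#' @return density in `[0, 1]`.
#' @export
graph_density <- function(net) {
  if (igraph::vcount(net) < 2) {
    stop("density undefined for fewer than 2 nodes", call. = FALSE)
  }
  igraph::edge_density(net)
}

#' Drop low-degree nodes
#'
#' Removes nodes whose degree in the input graph is below `min_degree` and
#' returns the induced subgraph. By default this is a single pass: degrees
#' are computed once on the input graph, so surviving nodes may end up with
#' fewer edges than `min_degree`. Set `iterative = TRUE` for the k-core
#' behaviour (repeat until stable).
#'
#' @param net an [igraph::igraph].
#' @param min_degree keep nodes with degree >= this value.
#' @param iterative repeat removal until every remaining node satisfies the
#'   threshold.
#' @return the filtered graph.
#' @export
filter_by_degree <- function(net, min_degree = 5, iterative = FALSE) {
  if (min_degree < 0) stop("min_degree must be >= 0", call. = FALSE)
  repeat {
    keep <- igraph::V(net)[igraph::degree(net) >= min_degree]
    done <- length(keep) == igraph::vcount(net)
    net <- igraph::induced_subgraph(net, keep)
    if (done || !iterative) break
  }
  net
}

#' Hub-gene table
#'
#' Ranks well-connected genes: nodes with degree at or above `min_degree`,
#' sorted by degree (descending), then betweenness (descending), then gene
#' id (ascending) for a deterministic order.
#'
#' @param ct centrality table from [centrality_table()].
#' @param min_degree hub threshold (default 8).
#' @return the filtered, ranked centrality table.
#' @export
hub_table <- function(ct, min_degree = 8) {
  hubs <- ct[ct$degree >= min_degree, , drop = FALSE]
  hubs <- hubs[order(-hubs$degree, -hubs$betweenness, hubs$gene), ,
               drop = FALSE]
  rownames(hubs) <- NULL
  hubs
}
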