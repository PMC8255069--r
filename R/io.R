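#' Read a count matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and gene ids
#' in the first column. Duplicate gene ids, non-integer entries and negative
#' counts are rejected with the offending row/column named.
#'
#' @param path TSV file path.
#' @return integer gene x sample matrix.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0) {
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    x <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(x) | x < 0 | abs(x - round(x)) > 1e-8)
    if (length(bad) > 0) {
      stop("invalid count at gene '", gene_ids[bad[1]], "', sample '",
           colnames(m)[j], "': ", m[bad[1], j], call. = FALSE)
    }
  }
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  m
}

#' Write a count matrix as TSV
#'
#' @param counts gene x sample matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `treatment`, `replicate`.
#' @return validated data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment", "replicate")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample ids in metadata", call. = FALSE)
  }
  df
}

#' Read a gene annotation table from TSV
#'
#' @param path TSV with columns `gene_id` and `category`
#'   (chemosensory / non_chemosensory / unannotated).
#' @return validated data frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(df))) {
    stop("annotations must have columns gene_id and category",
         call. = FALSE)
  }
  ok <- c("chemosensory", "non_chemosensory", "unannotated")
  bad <- setdiff(unique(df$category), ok)
  if (length(bad) > 0) {
    stop("unknown annotation categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicated gene ids in annotations", call. = FALSE)
  }
  df
}

#' Export a network as GraphML
#'
#' Writes the graph with its `category` node attribute and `weight` edge
#' attribute so it can be opened in external viewers (e.g. Cytoscape). The
#' file round-trips through standard GraphML readers.
#'
#' @param net a non-empty [igraph::igraph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  if (igraph::vcount(net) == 0) {
    stop("refusing to export an empty network", call. = FALSE)
  }
  if (is.null(igraph::vertex_attr(net, "category"))) {
    igraph::V(net)$category <- "unannotated"
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Export a network edge list as TSV
#'
#' @param net an [igraph::igraph] with edge weights.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  df <- data.frame(source = el[, 1], target = el[, 2], weight = w,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
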