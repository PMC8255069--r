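#' Absolute-correlation similarity matrix
#'
#' Computes the unsigned co-expression similarity `s_ij = |cor(x_i, x_j)|`
#' between all gene pairs. Genes with zero variance across samples are
#' dropped with a warning (their correlation is undefined).
#'
#' @param expr gene x sample matrix of expression values (typically
#'   `log2(normalized count + 1)`; see [log2_expression()]).
#' @param method correlation method passed to [stats::cor()].
#' @return symmetric matrix with entries in `[0, 1]` and unit diagonal.
#' @export
similarity_matrix <- function(expr, method = "pearson") {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (ncol(expr) < 3) {
    stop("need at least 3 samples to estimate correlations", call. = FALSE)
  }
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant gene(s) dropped before correlation",
            call. = FALSE)
    expr <- expr[v > 0, , drop = FALSE]
  }
  s <- abs(stats::cor(t(expr), method = method))
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Soft-threshold adjacency
#'
#' Raises each similarity to the power `beta`, shrinking weak correlations
#' toward zero while keeping the network weighted: `a_ij = s_ij^beta`.
#'
#' @param sim similarity matrix from [similarity_matrix()].
#' @param beta soft-thresholding power (>= 1). Default 12.
#' @return adjacency matrix with entries in `[0, 1]`; carries `beta` as an
#'   attribute.
#' @export
adjacency_matrix <- function(sim, beta = 12) {
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  a <- sim^beta
  attr(a, "beta") <- beta
  a
}

#' Scale-free topology fit index
#'
#' Measures how well the (weighted) degree distribution follows a power law:
#' connectivities are binned on a log scale, and `log10(p(k))` is regressed
#' on `log10(k)`. The index is `-sign(slope) * R^2`, positive when the
#' degree distribution decays with k.
#'
#' @param x an adjacency matrix (weighted connectivity `k_i = sum_j a_ij`
#'   is used), an [igraph::igraph] (node degree is used), or a numeric
#'   vector of connectivities.
#' @param n_bins number of equal-width bins on `log10(k)`.
#' @return the signed R-squared fit index.
#' @export
scale_free_fit <- function(x, n_bins = 10) {
  k <- if (inherits(x, "igraph")) {
    igraph::degree(x)
  } else if (is.matrix(x)) {
    rowSums(x) - diag(x)
  } else {
    as.numeric(x)
  }
  k <- k[k > 0]
  if (length(unique(k)) < 2) {
    stop("scale-free fit undefined: connectivities are all equal",
         call. = FALSE)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  p_k <- tapply(k, bin, length) / length(k)
  k_mean <- tapply(k, bin, mean)
  occupied <- !is.na(p_k) & p_k > 0
  if (sum(occupied) < 2) {
    stop("scale-free fit undefined: fewer than two occupied degree bins",
         call. = FALSE)
  }
  fit <- stats::lm(log10(p_k[occupied]) ~ log10(k_mean[occupied]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[[2]]) * r2
}

#' Choose a soft-thresholding power
#'
#' Evaluates the scale-free fit index for each candidate power and returns
#' the smallest power whose fit reaches `target_fit`; if none does, the
#' power with the maximal fit is returned. The full table is kept for
#' plotting and audit.
#'
#' @param expr gene x sample expression matrix.
#' @param powers candidate powers (default 1..20).
#' @param target_fit fit index considered sufficient (default 0.8).
#' @param n_bins bins for [scale_free_fit()].
#' @return list with `beta` (selected power) and `fit_table` (data frame
#'   with `power`, `fit`, `mean_k`, `median_k`, `max_k`).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_fit = 0.8,
                                n_bins = 10) {
  if (length(powers) == 0) stop("no candidate powers", call. = FALSE)
  sim <- similarity_matrix(expr)
  rows <- lapply(powers, function(b) {
    a <- sim^b
    k <- rowSums(a) - diag(a)
    fit <- tryCatch(scale_free_fit(k, n_bins = n_bins),
                    error = function(e) NA_real_)
    data.frame(power = b, fit = fit, mean_k = mean(k),
               median_k = stats::median(k), max_k = max(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$fit) & tab$fit >= target_fit)
  beta <- if (length(hit) > 0) {
    tab$power[hit[1]]
  } else if (all(is.na(tab$fit))) {
    powers[1]
  } else {
    tab$power[which.max(tab$fit)]
  }
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' Standard unsigned topological overlap: with self-adjacency removed,
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`. Two genes overlap when
#' they are connected and share neighbours. The diagonal is set to 1 by
#' convention; `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj adjacency matrix with entries in `[0, 1]`.
#' @return symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-8)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  a <- unclass(adj)
  attr(a, "beta") <- NULL
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  min_k <- outer(k, k, pmin)
  tom <- (l + a) / (min_k + 1 - a)
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Average-linkage gene tree
#'
#' Agglomerative hierarchical clustering of a dissimilarity matrix
#' (typically `1 - TOM`). A single-gene input yields a degenerate tree with
#' no merges.
#'
#' @param diss square symmetric non-negative dissimilarity matrix.
#' @param method linkage passed to [stats::hclust()] (default `"average"`).
#' @return an object of class `hclust`.
#' @export
cluster_gene_tree <- function(diss, method = "average") {
  if (!is.matrix(diss)) diss <- as.matrix(diss)
  if (any(!is.finite(diss))) {
    stop("dissimilarity matrix contains non-finite values", call. = FALSE)
  }
  if (!isSymmetric(unname(diss), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  if (nrow(diss) == 1) {
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), order = 1L,
                          labels = rownames(diss), method = method,
                          call = match.call(),
                          dist.method = "custom"),
                     class = "hclust"))
  }
  stats::hclust(stats::as.dist(diss), method = method)
}

#' Cut a gene tree into modules
#'
#' Height-scanning tree cut: static cuts are evaluated at every candidate
#' merge height up to `cut_height_quantile * max(merge height)`, and the
#' lowest cut producing the largest number of branches of size
#' `>= min_module_size` is kept. Scanning instead of fixing a single height
#' makes the cut robust to the top of the dendrogram, where unrelated genes
#' chain together at near-maximal dissimilarity; module branches sit well
#' below that regime. Genes outside a surviving branch get module 0
#' ("unassigned", grey). Modules are numbered by decreasing size (module 1
#' = largest, mirroring the conventional turquoise/blue/brown ordering).
#' Fragmented modules can be reunited afterwards with
#' [merge_close_modules()] and grown with [assign_by_membership()].
#'
#' @param tree an `hclust` tree from [cluster_gene_tree()].
#' @param min_module_size smallest allowed module (default 30 genes).
#' @param cut_height_quantile fraction of the maximal merge height capping
#'   the scanned cut heights (default 0.99).
#' @return data frame with `gene_id`, `module` (integer, 0 = unassigned)
#'   and `color`.
#' @export
cut_modules <- function(tree, min_module_size = 30,
                        cut_height_quantile = 0.99) {
  labels <- tree$labels
  if (is.null(labels)) labels <- sprintf("gene_%d", seq_along(tree$order))
  if (length(tree$height) == 0 ||
      max(tree$height) - min(tree$height) < 1e-12) {
    # no structure (single gene, or a flat tree with all-equal merge
    # heights): the whole set is one candidate module
    raw <- stats::setNames(rep(1L, length(labels)), labels)
  } else {
    hs <- sort(unique(tree$height))
    cap <- cut_height_quantile * max(hs)
    cands <- if (length(hs) > 1) {
      mids <- (hs[-length(hs)] + hs[-1]) / 2
      c(mids[mids <= cap], cap)
    } else {
      cap
    }
    if (length(cands) > 256) {
      cands <- cands[unique(round(seq(1, length(cands), length.out = 256)))]
    }
    cuts <- stats::cutree(tree, h = cands)
    if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
    n_big <- apply(cuts, 2, function(cl) sum(table(cl) >= min_module_size))
    raw <- cuts[, which.max(n_big)]  # lowest height attaining the maximum
  }
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  module <- integer(length(raw))
  if (length(keep) > 0) {
    kept_sizes <- sizes[keep]
    ord <- keep[order(-as.integer(kept_sizes), as.integer(keep))]
    for (i in seq_along(ord)) {
      module[raw == as.integer(ord[i])] <- i
    }
  }
  data.frame(gene_id = labels, module = module,
             color = module_color(module), stringsAsFactors = FALSE)
}

#' Assign unassigned genes by module membership
#'
#' Module membership (kME) of a gene is its correlation with a module
#' eigengene. Each unassigned gene joins the module with the highest
#' absolute membership, provided it reaches `min_kme`; eigengenes are
#' recomputed and the assignment repeated until no gene moves (at most
#' `max_passes` rounds). Genes below the threshold for every module stay
#' unassigned, so background genes are not forced into modules.
#'
#' @param expr gene x sample expression matrix covering all genes in
#'   `modules`.
#' @param modules module assignment (data frame or named vector).
#' @param min_kme minimal absolute eigengene correlation required to join
#'   a module (default 0.6).
#' @param max_passes maximal number of assignment rounds.
#' @return module assignment data frame in the format of [cut_modules()].
#' @export
assign_by_membership <- function(expr, modules, min_kme = 0.6,
                                 max_passes = 5) {
  mod <- .module_vector(modules)
  if (!any(mod > 0)) {
    return(data.frame(gene_id = names(mod), module = unname(mod),
                      color = module_color(mod), stringsAsFactors = FALSE))
  }
  for (pass in seq_len(max_passes)) {
    un <- which(mod == 0)
    if (length(un) == 0) break
    me <- module_eigengenes(expr, mod)
    kme <- suppressWarnings(stats::cor(t(expr[un, , drop = FALSE]), me))
    kme[!is.finite(kme)] <- 0
    best <- apply(abs(kme), 1, which.max)
    best_val <- apply(abs(kme), 1, max)
    join <- best_val >= min_kme
    if (!any(join)) break
    ids <- as.integer(sub("^ME", "", colnames(me)))
    mod[un[join]] <- ids[best[join]]
  }
  data.frame(gene_id = names(mod), module = unname(mod),
             color = module_color(mod), stringsAsFactors = FALSE)
}

#' Module colour names
#'
#' Maps size-ranked module numbers to the conventional colour labels
#' (0 = grey = unassigned, 1 = turquoise, 2 = blue, ...). Numbers beyond the
#' palette fall back to `"module<k>"`.
#'
#' @param module integer vector of module numbers.
#' @return character vector of colour names.
#' @export
module_color <- function(module) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue")
  out <- ifelse(module == 0, "grey",
                ifelse(module <= length(palette), palette[pmax(module, 1)],
                       paste0("module", module)))
  as.character(out)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' row-standardized gene x sample submatrix, i.e. the per-sample summary
#' profile explaining the most variance. The sign is fixed so the eigengene
#' correlates positively with the module's mean expression profile; a
#' single-gene module's eigengene is that gene's standardized profile.
#'
#' @param expr gene x sample expression matrix covering all module genes.
#' @param modules data frame from [cut_modules()] (columns `gene_id`,
#'   `module`), or a named integer vector.
#' @return sample x module matrix with columns `ME1`, `ME2`, ...; the
#'   fraction of variance explained is attached as attribute
#'   `var_explained`.
#' @export
module_eigengenes <- function(expr, modules) {
  mod <- .module_vector(modules)
  ids <- sort(unique(mod[mod > 0]))
  if (length(ids) == 0) stop("no named modules", call. = FALSE)
  me <- matrix(NA_real_, ncol(expr), length(ids),
               dimnames = list(colnames(expr), paste0("ME", ids)))
  varexp <- stats::setNames(numeric(length(ids)), paste0("ME", ids))
  for (j in seq_along(ids)) {
    genes <- names(mod)[mod == ids[j]]
    x <- expr[genes, , drop = FALSE]
    xs <- t(scale(t(x)))
    xs[!is.finite(xs)] <- 0  # constant genes contribute nothing
    if (nrow(xs) == 1) {
      me[, j] <- xs[1, ]
      varexp[j] <- 1
      next
    }
    sv <- svd(xs)
    v1 <- sv$v[, 1]
    ref <- colMeans(xs)
    s <- sum(v1 * ref)
    if (abs(s) < 1e-8) {
      # degenerate mean profile (e.g. perfectly anticorrelated genes):
      # anchor the sign on the first sizeable component instead
      s <- v1[which(abs(v1) > 1e-8)[1]]
    }
    if (s < 0) v1 <- -v1
    me[, j] <- v1
    varexp[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(me, "var_explained") <- varexp
  me
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengene dissimilarity `1 - cor(ME_i, ME_j)` falls below
#' `cut` are merged iteratively, closest pair first, recomputing eigengenes
#' after each merge. With all dissimilarities at or above `cut` the
#' assignment is returned unchanged (up to size-based renumbering), so the
#' operation is idempotent at a fixed cut.
#'
#' @param expr gene x sample expression matrix.
#' @param modules module assignment (data frame or named vector; see
#'   [module_eigengenes()]).
#' @param cut merge threshold on eigengene dissimilarity (default 0.25,
#'   i.e. modules over 75% correlated are merged).
#' @return module assignment data frame in the format of [cut_modules()].
#' @export
merge_close_modules <- function(expr, modules, cut = 0.25) {
  mod <- .module_vector(modules)
  repeat {
    ids <- sort(unique(mod[mod > 0]))
    if (length(ids) < 2 || cut <= 0) break
    me <- module_eigengenes(expr, mod)
    diss <- 1 - stats::cor(me)
    diag(diss) <- Inf
    if (min(diss) >= cut) break
    pair <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    from <- ids[max(pair)]
    to <- ids[min(pair)]
    mod[mod == from] <- to
  }
  # renumber by decreasing size for a canonical labelling
  ids <- sort(unique(mod[mod > 0]))
  sizes <- vapply(ids, function(i) sum(mod == i), integer(1))
  ord <- ids[order(-sizes, ids)]
  out <- integer(length(mod))
  for (i in seq_along(ord)) out[mod == ord[i]] <- i
  data.frame(gene_id = names(mod), module = out,
             color = module_color(out), stringsAsFactors = FALSE)
}

.module_vector <- function(modules) {
  if (is.data.frame(modules)) {
    stats::setNames(as.integer(modules$module), modules$gene_id)
  } else {
    stats::setNames(as.integer(modules), names(modules))
  }
}
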