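#' Remove genes that are low-count in most samples
#'
#' A gene is dropped when the proportion of samples with a count below
#' `min_count` is strictly greater than `sample_frac` (counts below 10 in
#' more than 90% of samples, by default). The operation is idempotent and
#' preserves gene order.
#'
#' @param counts non-negative integer gene x sample matrix.
#' @param min_count counts below this value are considered uninformative.
#' @param sample_frac drop a gene when low-count in more than this fraction
#'   of samples; must be in (0, 1].
#' @return the filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_count = 10, sample_frac = 0.9) {
  counts <- .validate_counts(counts)
  if (sample_frac <= 0 || sample_frac > 1) {
    stop("sample_frac must be in (0, 1]", call. = FALSE)
  }
  low_frac <- rowMeans(counts < min_count)
  keep <- low_frac <= sample_frac
  if (!any(keep)) {
    warning("all genes removed by low-count filter", call. = FALSE)
  }
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over genes with a
#' positive geometric mean, of the ratio of the sample's count to the gene's
#' geometric mean across samples (the median-of-ratios normalization used
#' for count data).
#'
#' @param counts non-negative count matrix (genes x samples).
#' @return positive numeric vector of length `ncol(counts)`, named by sample.
#' @export
size_factors <- function(counts) {
  counts <- .validate_counts(counts)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    stop("no gene has a nonzero count in every sample; ",
         "size factors are undefined", call. = FALSE)
  }
  sf <- apply(counts, 2, function(x) {
    exp(stats::median((log(x) - log_geo)[usable]))
  })
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors; computed with [size_factors()] when missing.
#' @return matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  sweep(counts, 2, sf, `/`)
}

#' Log2 expression values
#'
#' Convenience wrapper producing `log2(normalized count + 1)`, the expression
#' scale used throughout the co-expression and discretization stages.
#'
#' @inheritParams normalize_counts
#' @return gene x sample matrix of log2 expression values.
#' @export
log2_expression <- function(counts, sf = NULL) {
  log2(normalize_counts(counts, sf) + 1)
}

#' Differential expression screen (Welch test stand-in)
#'
#' A deliberately simple differential-expression engine used in place of a
#' negative-binomial GLM: counts are normalized by median-of-ratios size
#' factors, the log2 fold change is the log2 ratio of group mean normalized
#' counts (pseudocount 0.5), and the p-value comes from a two-sample Welch
#' t-test on `log2(normalized count + 1)` (pseudocount 1), adjusted with
#' Benjamini-Hochberg. Genes with zero variance in both groups get p = 1
#' when the group means agree.
#'
#' @param counts gene x sample count matrix.
#' @param metadata data frame with columns `sample_id` and `treatment`
#'   covering every column of `counts`.
#' @param contrast length-2 character vector `c(treatment, control)`;
#'   fold changes are treatment over control.
#' @return data frame with one row per gene: `gene_id`, `base_mean`,
#'   `log2_fold_change`, `p_value`, `p_adjusted`, `contrast`.
#' @export
differential_expression <- function(counts, metadata,
                                    contrast = c("attractant", "control")) {
  counts <- .validate_counts(counts)
  if (length(contrast) != 2) stop("contrast must have length 2", call. = FALSE)
  if (!all(c("sample_id", "treatment") %in% names(metadata))) {
    stop("metadata needs columns sample_id and treatment", call. = FALSE)
  }
  if (!all(colnames(counts) %in% metadata$sample_id)) {
    stop("metadata does not cover every sample", call. = FALSE)
  }
  trt <- metadata$treatment[match(colnames(counts), metadata$sample_id)]
  g1 <- which(trt == contrast[1])
  g2 <- which(trt == contrast[2])
  if (length(g1) < 2 || length(g2) < 2) {
    stop("each group in the contrast needs at least 2 replicates",
         call. = FALSE)
  }
  norm <- normalize_counts(counts)
  l2 <- log2(norm + 1)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  lfc <- log2((m1 + 0.5) / (m2 + 0.5))
  p <- .welch_rows(l2, g1, g2)
  data.frame(gene_id = rownames(counts),
             base_mean = rowMeans(norm),
             log2_fold_change = lfc,
             p_value = p,
             p_adjusted = adjust_bh(p),
             contrast = paste(contrast, collapse = "_vs_"),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized two-sample Welch t-test on the rows of x.
.welch_rows <- function(x, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t_stat), df)
  # degenerate variance: equal constants -> no evidence; unequal -> certain
  zero_se <- se2 <= 0 | !is.finite(t_stat) | !is.finite(df)
  p[zero_se] <- ifelse(abs(m1 - m2)[zero_se] < 1e-12, 1, 0)
  unname(p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment mapped back to the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
adjust_bh <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select differentially expressed genes
#'
#' Keeps genes with adjusted p-value strictly below `max_fdr` and at least a
#' `min_fold`-fold change in either direction.
#'
#' @param results data frame from [differential_expression()].
#' @param max_fdr FDR cutoff (strict `<`).
#' @param min_fold minimum fold change; compared as
#'   `abs(log2_fold_change) >= log2(min_fold)`.
#' @return character vector of selected gene ids.
#' @export
select_de_genes <- function(results, max_fdr = 0.05, min_fold = 2) {
  if (nrow(results) == 0) return(character(0))
  keep <- results$p_adjusted < max_fdr &
    abs(results$log2_fold_change) >= log2(min_fold)
  results$gene_id[keep]
}

.validate_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%d", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids", call. = FALSE)
  }
  counts
}
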