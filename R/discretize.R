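#' Equal-frequency interval boundaries for one gene
#'
#' Five-step equal-frequency discretization: sort the values, split them
#' into `k` contiguous groups whose sizes differ by at most one, and place
#' each boundary at the midpoint between the maximum of one group and the
#' minimum of the next. When `n` is not divisible by `k` the extra elements
#' go to the later (upper) bins, so with two bins the over-expressed bin is
#' never smaller than the under-expressed bin. Ties that would straddle a
#' boundary are absorbed into the lower bin and the remaining cut points
#' shift accordingly.
#'
#' @param values numeric vector (one gene across samples), `n >= k`.
#' @param k number of bins (>= 2).
#' @return object of class `eq_freq_bins`: list with `boundaries`
#'   (strictly increasing, length `k - 1`) and `k`.
#' @export
equal_frequency_bins <- function(values, k = 2) {
  n <- length(values)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k values", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  sv <- sort(values)
  if (sv[1] == sv[n]) {
    stop("all values are equal; no valid boundary exists", call. = FALSE)
  }
  base <- n %/% k
  extra <- n %% k
  sizes <- base + as.integer(seq_len(k) > k - extra)  # extras to upper bins
  cuts <- cumsum(sizes)[seq_len(k - 1)]
  boundaries <- numeric(k - 1)
  prev <- 0L
  for (j in seq_len(k - 1)) {
    c_j <- max(cuts[j], prev + 1L)
    while (c_j < n && sv[c_j] == sv[c_j + 1L]) c_j <- c_j + 1L
    if (c_j >= n) {
      stop("ties prevent forming ", k, " non-empty bins", call. = FALSE)
    }
    boundaries[j] <- (sv[c_j] + sv[c_j + 1L]) / 2
    prev <- c_j
  }
  structure(list(boundaries = boundaries, k = as.integer(k)),
            class = "eq_freq_bins")
}

#' Discretize an expression matrix into transactions
#'
#' Applies [equal_frequency_bins()] to every gene and maps each sample's
#' value to its interval index (0-based). With the default `k = 2` the
#' result is the binary over-expression matrix: 0 = under-expressed,
#' 1 = over-expressed. Genes for which no valid boundary exists (constant,
#' or too tied) are dropped with a warning. Because the procedure depends
#' only on value ranks, any strictly increasing transform of a gene's
#' values yields identical labels.
#'
#' @param expr gene x sample expression matrix.
#' @param k number of bins per gene (default 2).
#' @return integer sample x gene matrix of interval indices in
#'   `0 ... k - 1`.
#' @export
discretize_matrix <- function(expr, k = 2) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (is.null(rownames(expr))) {
    rownames(expr) <- sprintf("gene_%d", seq_len(nrow(expr)))
  }
  labels <- vector("list", nrow(expr))
  ok <- logical(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    bins <- tryCatch(equal_frequency_bins(expr[i, ], k = k),
                     error = function(e) NULL)
    if (is.null(bins)) next
    labels[[i]] <- findInterval(expr[i, ], bins$boundaries)
    ok[i] <- TRUE
  }
  if (!all(ok)) {
    warning(sum(!ok), " gene(s) dropped: no valid equal-frequency bins",
            call. = FALSE)
  }
  if (!any(ok)) {
    return(matrix(integer(0), ncol(expr), 0,
                  dimnames = list(colnames(expr), character(0))))
  }
  out <- do.call(cbind, labels[ok])
  dimnames(out) <- list(colnames(expr), rownames(expr)[ok])
  storage.mode(out) <- "integer"
  out
}

#' Transactions from a binary incidence matrix
#'
#' One transaction per sample, containing exactly the genes marked 1
#' (over-expressed) in that sample. Under-expression is absence, matching
#' the market-basket view of the data.
#'
#' @param db binary sample x gene matrix (from [discretize_matrix()] with
#'   `k = 2`).
#' @return named list of character vectors, one per sample.
#' @export
to_transactions <- function(db) {
  if (!all(db %in% c(0, 1))) {
    stop("transactions require a binary matrix (k = 2)", call. = FALSE)
  }
  items <- colnames(db)
  out <- apply(db == 1, 1, function(r) items[r], simplify = FALSE)
  stats::setNames(out, rownames(db))
}

#' Write transactions in basket format
#'
#' One line per transaction: `sample_id<TAB>item1,item2,...`. Compatible
#' with common association-rule-mining tool input.
#'
#' @param db binary sample x gene matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_basket <- function(db, path) {
  tx <- to_transactions(db)
  lines <- vapply(names(tx), function(s) {
    paste0(s, "\t", paste(tx[[s]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
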