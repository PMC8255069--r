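# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use naive definitions (exhaustive
# enumeration, matrix powers) rather than the algorithms under test.

# Step-up FDR adjustment straight from the definition:
# padj_(i) = min_{j >= i} min(1, p_(j) * m / j), mapped back to input order.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  padj <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- padj
  out
}

# Support of every non-empty itemset by exhaustive enumeration (m <= 15).
# Returns a named vector keyed by the sorted items joined with "\x1f".
bf_all_supports <- function(db) {
  db <- db != 0
  items <- colnames(db)
  m <- length(items)
  n <- nrow(db)
  out <- numeric(0)
  for (mask in seq_len(2^m - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    sub <- sort(items[sel])
    cnt <- sum(rowSums(db[, sel, drop = FALSE]) == sum(sel))
    out[paste(sub, collapse = "\x1f")] <- cnt / n
  }
  out
}

# All-pairs shortest-path distances and path counts from matrix powers:
# the number of walks of length d(s,t) between s and t equals the number
# of shortest paths.
bf_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  S <- matrix(0, n, n)
  diag(S) <- 1
  cur <- diag(n)
  for (k in seq_len(n)) {
    cur <- cur %*% A
    new <- (D == Inf) & (cur > 0)
    diag(new) <- FALSE
    D[new] <- k
    S[new] <- cur[new]
  }
  list(D = D, S = S)
}

# Normalized betweenness from the path-count identity
# sigma_st(v) = sigma_sv * sigma_vt when d(s,v) + d(v,t) = d(s,t).
bf_betweenness <- function(A) {
  ps <- bf_paths(A)
  D <- ps$D; S <- ps$S
  n <- nrow(A)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          tot <- tot + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
    btw[v] <- tot / ((n - 1) * (n - 2) / 2)
  }
  btw
}

# Closeness per component: reachable count over summed distances.
bf_closeness <- function(A) {
  D <- bf_paths(A)$D
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
}

# Local clustering coefficient by direct neighbourhood counting.
bf_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
}

# Random symmetric adjacency matrix with entries in [0, 1].
rand_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%d", seq_len(n)), sprintf("g%d", seq_len(n)))
  a
}

# Random transaction database as a logical matrix.
rand_db <- function(n_trans, n_items, p = 0.5) {
  matrix(stats::runif(n_trans * n_items) < p, n_trans, n_items,
         dimnames = list(sprintf("t%d", seq_len(n_trans)),
                         letters[seq_len(n_items)]))
}

# Frequent itemsets as a canonical named support vector for comparison.
itemsets_as_vector <- function(fi) {
  stats::setNames(fi$support,
                  vapply(fi$items, paste, "", collapse = "\x1f"))
}
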