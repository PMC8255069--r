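#' Support of an itemset
#'
#' Exact fraction of transactions containing every item of the set. The
#' empty itemset has support 1 (it is contained in every transaction);
#' items absent from the database contribute support 0.
#'
#' @param items character vector of item (gene) names.
#' @param db binary/logical transaction x item incidence matrix.
#' @return support in `[0, 1]`.
#' @export
itemset_support <- function(items, db) {
  if (nrow(db) == 0) stop("empty transaction database", call. = FALSE)
  if (length(items) == 0) return(1)
  idx <- match(items, colnames(db))
  if (anyNA(idx)) return(0)
  mean(rowSums(db[, idx, drop = FALSE] != 0) == length(items))
}

#' Apriori frequent-itemset mining
#'
#' Level-wise search: frequent single items first, then candidate
#' `(k+1)`-itemsets joined from frequent k-itemsets sharing a `(k-1)`-prefix
#' and pruned unless every k-subset is frequent (anti-monotonicity of
#' support). Support is compared on transaction counts
#' (`count >= ceiling(min_support * |D|)`), so an exact threshold such as
#' 0.5 on an even number of transactions behaves inclusively without
#' floating-point wobble.
#'
#' @param db binary/logical transaction x item incidence matrix.
#' @param min_support minimal support, in (0, 1].
#' @param max_len maximal itemset size explored (default 5, covering rules
#'   with four antecedent items and one consequent).
#' @return data frame of class `frequent_itemsets` with columns `items`
#'   (list of sorted character vectors), `size`, `count` and `support`,
#'   ordered by size then lexicographically. The number of transactions is
#'   attached as attribute `n_transactions`.
#' @export
apriori <- function(db, min_support = 0.5, max_len = 5) {
  n <- nrow(db)
  if (n < 1) stop("empty transaction database", call. = FALSE)
  if (min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]", call. = FALSE)
  }
  db <- db != 0
  min_count <- max(1L, as.integer(ceiling(min_support * n - 1e-9)))

  counts1 <- colSums(db)
  items1 <- sort(colnames(db)[counts1 >= min_count])
  sets <- lapply(items1, identity)
  counts <- as.integer(counts1[items1])
  all_sets <- sets
  all_counts <- counts

  k <- 1L
  while (length(sets) >= 2 && k < max_len) {
    prev_keys <- vapply(sets, paste, "", collapse = "\x1f")
    cands <- .apriori_join(sets, k, prev_keys)
    if (length(cands) == 0) break
    new_counts <- vapply(cands, function(s) {
      idx <- match(s, colnames(db))
      sum(rowSums(db[, idx, drop = FALSE]) == length(s))
    }, numeric(1))
    keep <- new_counts >= min_count
    sets <- cands[keep]
    counts <- as.integer(new_counts[keep])
    all_sets <- c(all_sets, sets)
    all_counts <- c(all_counts, counts)
    k <- k + 1L
  }

  size <- lengths(all_sets)
  key <- vapply(all_sets, paste, "", collapse = "\x1f")
  ord <- order(size, key)
  out <- data.frame(size = size[ord], count = all_counts[ord],
                    support = all_counts[ord] / n)
  out$items <- all_sets[ord]
  out <- out[, c("items", "size", "count", "support")]
  attr(out, "n_transactions") <- n
  class(out) <- c("frequent_itemsets", "data.frame")
  out
}

# Join frequent k-itemsets sharing a (k-1)-prefix; prune candidates with an
# infrequent k-subset.
.apriori_join <- function(sets, k, prev_keys) {
  prefix <- vapply(sets, function(s) paste(s[-k], collapse = "\x1f"), "")
  lasts <- vapply(sets, function(s) s[k], "")
  cands <- list()
  for (g in split(seq_along(sets), prefix)) {
    if (length(g) < 2) next
    g <- g[order(lasts[g])]
    for (i in seq_len(length(g) - 1)) {
      for (j in (i + 1):length(g)) {
        cand <- c(sets[[g[i]]], lasts[g[j]])
        ok <- TRUE
        for (drop in seq_len(k - 1)) {
          if (!(paste(cand[-drop], collapse = "\x1f") %in% prev_keys)) {
            ok <- FALSE
            break
          }
        }
        if (ok) cands[[length(cands) + 1L]] <- cand
      }
    }
  }
  cands
}

#' Association rules from frequent itemsets
#'
#' For every frequent itemset Z with at least two items and every non-empty
#' proper subset X of Z, the rule X => Z\\X is emitted when its confidence
#' `supp(Z) / supp(X)` reaches `min_confidence`. Support of a rule is the
#' support of Z; lift is `confidence / supp(Y)`. All measures are computed
#' from the exact transaction counts stored with the itemsets. Rules are
#' ordered by lift (descending), support (descending), then rule text, and
#' given stable ids.
#'
#' @param itemsets result of [apriori()].
#' @param min_confidence minimal confidence (default 0.99).
#' @return data frame with `rule_id`, `antecedent` and `consequent`
#'   (lists of character vectors), `support`, `confidence`, `lift`,
#'   `rule_text`.
#' @export
generate_rules <- function(itemsets, min_confidence = 0.99) {
  n <- attr(itemsets, "n_transactions")
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(itemsets))) {
    assign(paste(itemsets$items[[i]], collapse = "\x1f"),
           itemsets$count[i], envir = lookup)
  }
  ante <- list(); cons <- list()
  supp <- numeric(0); conf <- numeric(0); lift <- numeric(0)
  for (i in which(itemsets$size >= 2)) {
    z <- itemsets$items[[i]]
    c_z <- itemsets$count[i]
    for (r in seq_len(length(z) - 1)) {
      subs <- utils::combn(z, r, simplify = FALSE)
      for (x in subs) {
        y <- setdiff(z, x)
        c_x <- get(paste(x, collapse = "\x1f"), envir = lookup)
        c_y <- get(paste(y, collapse = "\x1f"), envir = lookup)
        cf <- c_z / c_x
        if (cf >= min_confidence - 1e-12) {
          ante[[length(ante) + 1L]] <- x
          cons[[length(cons) + 1L]] <- y
          supp <- c(supp, c_z / n)
          conf <- c(conf, cf)
          lift <- c(lift, (c_z * n) / (c_x * c_y))
        }
      }
    }
  }
  txt <- mapply(function(x, y) {
    paste0("{", paste(x, collapse = ","), "} => {",
           paste(y, collapse = ","), "}")
  }, ante, cons, USE.NAMES = FALSE)
  if (length(ante) == 0) txt <- character(0)
  ord <- order(-lift, -supp, txt)
  out <- data.frame(rule_id = seq_along(ord),
                    support = supp[ord], confidence = conf[ord],
                    lift = lift[ord],
                    rule_text = as.character(txt[ord]),
                    stringsAsFactors = FALSE)
  out$antecedent <- ante[ord]
  out$consequent <- cons[ord]
  out[, c("rule_id", "antecedent", "consequent", "support", "confidence",
          "lift", "rule_text")]
}

#' Filter rules by lift
#'
#' Retains rules with `lift >= min_lift` (inclusive). Lift above 1 indicates
#' that antecedent and consequent occur together more often than expected
#' under independence.
#'
#' @param rules data frame from [generate_rules()].
#' @param min_lift minimal lift (default 2).
#' @return the filtered rule data frame.
#' @export
filter_rules <- function(rules, min_lift = 2) {
  rules[rules$lift >= min_lift - 1e-9, , drop = FALSE]
}
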