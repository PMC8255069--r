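#' Guilt-by-association function prediction
#'
#' Flags unannotated genes that co-mine with annotated genes. Antecedent and
#' consequent membership are treated symmetrically: for each unannotated
#' gene appearing in any rule, its annotated partners are counted once per
#' rule per partner, and the predicted category is the majority category of
#' those partner occurrences. A tie reports all tied categories and sets the
#' ambiguous flag. Genes whose rules contain no annotated partner are
#' excluded (no evidence). Genes present in rules but missing from the
#' annotation table are treated as unannotated, with a warning.
#'
#' @param rules data frame from [generate_rules()] (typically after
#'   [filter_rules()]).
#' @param annotations data frame with columns `gene_id` and `category`
#'   (`chemosensory`, `non_chemosensory` or `unannotated`).
#' @return data frame with `gene_id`, `predicted_category` (";"-joined when
#'   tied), `ambiguous`, `n_rules`, `n_partners` (distinct annotated partner
#'   genes), `supporting_rules` (";"-joined rule ids).
#' @export
predict_functions <- function(rules, annotations) {
  if (!all(c("gene_id", "category") %in% names(annotations))) {
    stop("annotations need columns gene_id and category", call. = FALSE)
  }
  category <- stats::setNames(annotations$category, annotations$gene_id)
  if (nrow(rules) == 0) {
    return(data.frame(gene_id = character(0),
                      predicted_category = character(0),
                      ambiguous = logical(0), n_rules = integer(0),
                      n_partners = integer(0),
                      supporting_rules = character(0),
                      stringsAsFactors = FALSE))
  }
  rule_genes <- mapply(function(x, y) sort(unique(c(x, y))),
                       rules$antecedent, rules$consequent, SIMPLIFY = FALSE)
  all_genes <- unique(unlist(rule_genes))
  missing <- setdiff(all_genes, names(category))
  if (length(missing) > 0) {
    warning(length(missing), " gene(s) in rules missing from the ",
            "annotation table; treated as unannotated", call. = FALSE)
    category[missing] <- "unannotated"
  }

  # per unannotated gene: tally annotated partner occurrences across rules
  acc <- list()
  for (i in seq_along(rule_genes)) {
    genes <- rule_genes[[i]]
    cats <- category[genes]
    unann <- genes[cats == "unannotated"]
    partners <- genes[cats != "unannotated"]
    if (length(unann) == 0 || length(partners) == 0) next
    for (g in unann) {
      rec <- acc[[g]]
      if (is.null(rec)) {
        rec <- list(rules = integer(0), partners = character(0),
                    cat_counts = integer(0))
      }
      rec$rules <- c(rec$rules, rules$rule_id[i])
      rec$partners <- c(rec$partners, partners)
      tab <- table(unname(category[partners]))
      for (cn in names(tab)) {
        rec$cat_counts[cn] <- sum(rec$cat_counts[cn], tab[[cn]], na.rm = TRUE)
      }
      acc[[g]] <- rec
    }
  }
  if (length(acc) == 0) {
    return(predict_functions(rules[0, , drop = FALSE], annotations))
  }

  rows <- lapply(sort(names(acc)), function(g) {
    rec <- acc[[g]]
    cc <- rec$cat_counts
    top <- sort(names(cc)[cc == max(cc)])
    data.frame(gene_id = g,
               predicted_category = paste(top, collapse = ";"),
               ambiguous = length(top) > 1,
               n_rules = length(unique(rec$rules)),
               n_partners = length(unique(rec$partners)),
               supporting_rules = paste(sort(unique(rec$rules)),
                                        collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
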