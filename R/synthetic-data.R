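#' Simulation configuration for synthetic RNA-seq counts
#'
#' Bundles and validates all parameters of [simulate_counts()]. The default
#' design mirrors a small antennal RNA-seq experiment: three treatments
#' (control, attractant, repellent) with three replicates each, planted
#' co-expression modules driven by a shared latent factor, a subset of genes
#' differentially expressed in the attractant treatment, and small planted
#' co-regulated gene groups engineered to binarize jointly under
#' equal-frequency discretization.
#'
#' @param n_genes total number of genes.
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per planted module. `n_modules * module_size`
#'   (plus the rule-group budget) must not exceed `n_genes`.
#' @param n_samples number of samples; treatments are assigned in balanced
#'   rotation over control/attractant/repellent. Default 9 (3 x 3 design).
#' @param within_module_cor target latent correlation between genes of the
#'   same module, in `[0, 1]`.
#' @param de_gene_frac fraction of genes planted as differentially expressed.
#' @param de_log2fc planted absolute log2 fold change (>= 1 mirrors a
#'   two-fold change) applied in the attractant treatment.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + nb_dispersion * mu^2`); 0 falls back to Poisson sampling.
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   per-gene baseline expression level.
#' @param bio_log_sd natural-log sd of per-sample biological variation
#'   around the gene baseline.
#' @param n_rule_groups number of planted co-regulated ("rule") gene groups.
#' @param rule_group_size genes per rule group; drawn from the background
#'   (non-module) genes.
#' @param rule_group_log2fc log2 fold change separating the group's "on"
#'   samples from its "off" samples.
#' @param library_size_log_sd natural-log sd of per-sample library-size
#'   factors.
#' @param seed integer RNG seed; identical seed and configuration give
#'   bit-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_counts()]
#' @export
sim_config <- function(n_genes = 200L,
                       n_modules = 4L,
                       module_size = 30L,
                       n_samples = 9L,
                       within_module_cor = 0.7,
                       de_gene_frac = 0.1,
                       de_log2fc = 2,
                       nb_dispersion = 0.05,
                       baseline_log_mean = log(150),
                       baseline_log_sd = 1,
                       bio_log_sd = 1,
                       n_rule_groups = 1L,
                       rule_group_size = 5L,
                       rule_group_log2fc = 3,
                       library_size_log_sd = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size), n_samples = as.integer(n_samples),
    within_module_cor = within_module_cor, de_gene_frac = de_gene_frac,
    de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    bio_log_sd = bio_log_sd, n_rule_groups = as.integer(n_rule_groups),
    rule_group_size = as.integer(rule_group_size),
    rule_group_log2fc = rule_group_log2fc,
    library_size_log_sd = library_size_log_sd, seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L || cfg$n_samples < 2L) {
    stop("need at least 1 gene and 2 samples", call. = FALSE)
  }
  if (cfg$n_modules < 0L || cfg$module_size < 0L) {
    stop("module counts must be non-negative", call. = FALSE)
  }
  budget <- cfg$n_modules * cfg$module_size +
    cfg$n_rule_groups * cfg$rule_group_size
  if (budget > cfg$n_genes) {
    stop("module/rule-group budget (", budget, " genes) exceeds n_genes (",
         cfg$n_genes, ")", call. = FALSE)
  }
  for (f in c("within_module_cor", "de_gene_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(f, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (is.na(cfg$seed)) stop("seed is required", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate an RNA-seq count matrix with known ground truth
#'
#' Counts are drawn from a negative-binomial distribution around log-normal
#' latent means. Genes of the same planted module share a per-module Gaussian
#' factor with loading `sqrt(within_module_cor)`, giving a tunable latent
#' correlation. Planted DE genes have their mean multiplied by
#' `2^de_log2fc` (random sign) in the attractant samples. Planted rule-group
#' genes follow a shared on/off profile: `ceiling(n_samples / 2)` "on" samples
#' at `2^rule_group_log2fc` times baseline with only mild noise, so the whole
#' group lands in the upper bin of a two-bin equal-frequency discretization
#' in the same samples.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{counts}{integer gene x sample matrix with dimnames.}
#'     \item{metadata}{data frame with `sample_id`, `treatment`, `replicate`.}
#'     \item{truth}{ground truth: `module_of_gene` (named integer, 0 =
#'       background), `de_genes` (data frame gene_id/log2fc/treatment),
#'       `rule_groups` (list of gene-id vectors), `rule_group_on_samples`
#'       (list of sample-id vectors), `annotations` (data frame
#'       gene_id/category with rule-group genes split between
#'       chemosensory and unannotated), `size_factors` (true per-sample
#'       library-size factors).}
#'   }
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, n_modules = 1,
#'                                   module_size = 10, seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    ng <- config$n_genes
    ns <- config$n_samples
    gene_ids <- sprintf("gene_%03d", seq_len(ng))
    sample_ids <- sprintf("sample_%02d", seq_len(ns))

    trt_levels <- c("control", "attractant", "repellent")
    treatment <- rep(trt_levels, length.out = ns)
    treatment <- treatment[order(match(treatment, trt_levels))]
    replicate <- stats::ave(seq_len(ns), treatment, FUN = seq_along)
    metadata <- data.frame(sample_id = sample_ids, treatment = treatment,
                           replicate = as.integer(replicate),
                           stringsAsFactors = FALSE)

    # planted structure: modules first, then rule groups from the background
    module_of_gene <- integer(ng)
    names(module_of_gene) <- gene_ids
    idx <- 1L
    for (m in seq_len(config$n_modules)) {
      module_of_gene[idx:(idx + config$module_size - 1L)] <- m
      idx <- idx + config$module_size
    }
    rule_groups <- list()
    for (r in seq_len(config$n_rule_groups)) {
      rule_groups[[r]] <- gene_ids[idx:(idx + config$rule_group_size - 1L)]
      idx <- idx + config$rule_group_size
    }

    # latent log-scale means
    mu_g <- stats::rnorm(ng, config$baseline_log_mean, config$baseline_log_sd)
    z <- matrix(stats::rnorm(ng * ns), ng, ns)
    for (m in seq_len(config$n_modules)) {
      rows <- which(module_of_gene == m)
      # factor standardized across samples so the realized within-module
      # correlation tracks the target instead of the factor's sampled
      # variance; loadings spread around sqrt(cor) so that connectivities
      # vary smoothly across module genes
      f <- as.numeric(scale(stats::rnorm(ns)))
      lambda <- pmin(0.995, sqrt(config$within_module_cor) *
                       stats::runif(length(rows), 0.9, 1.1))
      z[rows, ] <- lambda * matrix(f, length(rows), ns, byrow = TRUE) +
        sqrt(1 - lambda^2) * z[rows, ]
    }
    log_mu <- mu_g + config$bio_log_sd * z

    # planted differential expression in the attractant treatment
    n_de <- round(config$de_gene_frac * ng)
    de_pool <- setdiff(gene_ids, unlist(rule_groups))
    de_ids <- sort(sample(de_pool, min(n_de, length(de_pool))))
    de_sign <- sample(c(-1, 1), length(de_ids), replace = TRUE)
    att <- which(metadata$treatment == "attractant")
    if (length(de_ids) > 0 && length(att) > 0) {
      rows <- match(de_ids, gene_ids)
      log_mu[rows, att] <- log_mu[rows, att] +
        de_sign * config$de_log2fc * log(2)
    }
    de_genes <- data.frame(gene_id = de_ids,
                           log2fc = de_sign * config$de_log2fc,
                           treatment = rep("attractant", length(de_ids)),
                           stringsAsFactors = FALSE)

    # planted co-regulated groups: shared on/off profile, tight noise.
    # The "on" block has ceiling(ns / 2) samples so it coincides with the
    # upper bin of a two-bin equal-frequency discretization.
    n_on <- max(1L, as.integer(ceiling(ns / 2)))
    on_samples <- list()
    for (r in seq_along(rule_groups)) {
      on <- sort(sample(ns, n_on))
      on_samples[[r]] <- sample_ids[on]
      rows <- match(rule_groups[[r]], gene_ids)
      prof <- ifelse(seq_len(ns) %in% on, config$rule_group_log2fc * log(2), 0)
      log_mu[rows, ] <- mu_g[rows] +
        matrix(prof, length(rows), ns, byrow = TRUE) +
        0.1 * matrix(stats::rnorm(length(rows) * ns), length(rows), ns)
    }

    # library-size factors and negative-binomial sampling
    lf <- stats::rnorm(ns, 0, config$library_size_log_sd)
    mu <- exp(sweep(log_mu, 2, lf, `+`))
    counts <- if (config$nb_dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    counts <- matrix(as.integer(counts), ng, ns,
                     dimnames = list(gene_ids, sample_ids))

    annotations <- .sim_annotations(gene_ids, rule_groups)
    list(counts = counts, metadata = metadata,
         truth = list(module_of_gene = module_of_gene,
                      de_genes = de_genes,
                      rule_groups = rule_groups,
                      rule_group_on_samples = on_samples,
                      annotations = annotations,
                      size_factors = stats::setNames(exp(lf), sample_ids)))
  })
}

# Rule-group genes split ~60/40 between annotated chemosensory and
# unannotated; everything else is non-chemosensory.
.sim_annotations <- function(gene_ids, rule_groups) {
  category <- rep("non_chemosensory", length(gene_ids))
  names(category) <- gene_ids
  for (grp in rule_groups) {
    n_chem <- ceiling(0.6 * length(grp))
    category[grp[seq_len(n_chem)]] <- "chemosensory"
    if (n_chem < length(grp)) {
      category[grp[(n_chem + 1L):length(grp)]] <- "unannotated"
    }
  }
  data.frame(gene_id = gene_ids, category = unname(category),
             stringsAsFactors = FALSE)
}

#' Simulate a binary transaction database with planted itemsets
#'
#' Item occurrences start as independent Bernoulli(`noise_prob`) noise; each
#' planted itemset is then inserted jointly into a transaction with
#' probability `itemset_prob`, so its observed support is at least about
#' `itemset_prob`.
#'
#' @param n_transactions,n_items database dimensions. Items are named
#'   `item_1 ... item_n` unless planted itemsets introduce other names.
#' @param planted_itemsets list of character vectors of item names.
#' @param itemset_prob probability of jointly inserting each planted itemset
#'   into a transaction.
#' @param noise_prob background occurrence probability per item.
#' @param seed integer RNG seed.
#' @return logical transaction x item incidence matrix with dimnames.
#' @export
simulate_transactions <- function(n_transactions, n_items,
                                  planted_itemsets = list(),
                                  itemset_prob = 0.6, noise_prob = 0.05,
                                  seed = 1L) {
  if (itemset_prob < 0 || itemset_prob > 1 || noise_prob < 0 || noise_prob > 1) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  items <- sprintf("item_%d", seq_len(n_items))
  extra <- setdiff(unique(unlist(planted_itemsets)), items)
  if (length(extra) > 0 && length(unlist(planted_itemsets)) > 0 &&
      !all(unlist(planted_itemsets) %in% c(items, extra))) {
    stop("planted itemsets reference unknown items", call. = FALSE)
  }
  items <- c(items, extra)
  withr::with_seed(as.integer(seed), {
    db <- matrix(stats::runif(n_transactions * length(items)) < noise_prob,
                 n_transactions, length(items),
                 dimnames = list(sprintf("t_%d", seq_len(n_transactions)),
                                 items))
    for (set in planted_itemsets) {
      hit <- stats::runif(n_transactions) < itemset_prob
      db[hit, set] <- TRUE
    }
    db
  })
}

#' Generate small reference graphs for testing network metrics
#'
#' @param kind one of `"path"`, `"star"`, `"complete"`, `"erdos_renyi"`,
#'   `"preferential_attachment"`.
#' @param n number of nodes (>= 1). For `"star"` the centre is node 1.
#' @param p edge probability (Erdos-Renyi only).
#' @param m edges added per step (preferential attachment only).
#' @param seed integer RNG seed (random graphs only).
#' @return an undirected [igraph::igraph] object.
#' @export
simulate_graph <- function(kind = c("path", "star", "complete", "erdos_renyi",
                                    "preferential_attachment"),
                           n, p = 0.1, m = 2, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  switch(kind,
    path = igraph::make_ring(n, circular = FALSE),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    complete = igraph::make_full_graph(n),
    erdos_renyi = withr::with_seed(as.integer(seed),
                                   igraph::sample_gnp(n, p)),
    preferential_attachment = withr::with_seed(
      as.integer(seed), igraph::sample_pa(n, m = m, directed = FALSE))
  )
}
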