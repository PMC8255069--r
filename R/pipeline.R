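#' Pipeline configuration
#'
#' Collects and validates every stage parameter of [run_pipeline()].
#' Defaults are the study settings: counts below 10 in more than 90% of
#' samples filtered out, FDR < 0.05 with at least a two-fold change,
#' soft-thresholding power 12 (or picked from 1..20 when `beta = NULL`),
#' minimum module size 30, eigengene merge cut 0.25, degree filter 5, hub
#' threshold 8, two equal-frequency bins, and rule mining at support 0.5,
#' confidence 0.99, lift >= 2.
#'
#' Unknown arguments are rejected by normal argument matching, so a typo in
#' a parameter name fails before any stage runs.
#'
#' @param counts gene x sample count matrix (or a TSV path).
#' @param metadata sample metadata data frame (or a TSV path).
#' @param annotations optional gene annotation data frame (or TSV path);
#'   when present the prediction stage runs.
#' @param out_dir directory for stage artifacts.
#' @param contrast DE contrast, `c(treatment, control)`.
#' @param min_count,sample_frac low-count filter (see [filter_low_counts()]).
#' @param max_fdr,min_fold DE selection (see [select_de_genes()]).
#' @param beta soft power; `NULL` to pick from `powers`.
#' @param powers,target_fit candidates for [pick_soft_threshold()].
#' @param min_module_size,cut_height_quantile,merge_cut,min_kme module
#'   detection (see [cut_modules()], [merge_close_modules()] and
#'   [assign_by_membership()]).
#' @param edge_threshold,min_degree,hub_degree network stage (see
#'   [build_network()], [filter_by_degree()], [hub_table()]).
#' @param bins equal-frequency bins per gene.
#' @param min_support,min_confidence,min_lift,max_len rule mining.
#' @param gene_universe genes to discretize: `"network"` (nodes of the
#'   thresholded network), `"modules"` (all module-assigned genes) or
#'   `"all"` (every filtered gene).
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic given its inputs).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, annotations = NULL,
                            out_dir = tempfile("coexrules_run_"),
                            contrast = c("attractant", "control"),
                            min_count = 10, sample_frac = 0.9,
                            max_fdr = 0.05, min_fold = 2,
                            beta = NULL, powers = 1:20, target_fit = 0.8,
                            min_module_size = 30,
                            cut_height_quantile = 0.99, merge_cut = 0.25,
                            min_kme = 0.6,
                            edge_threshold = 0.2, min_degree = 5,
                            hub_degree = 8, bins = 2,
                            min_support = 0.5, min_confidence = 0.99,
                            min_lift = 2, max_len = 5,
                            gene_universe = c("network", "modules", "all"),
                            seed = 1L) {
  if (is.character(counts)) counts <- read_count_matrix(counts)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  gene_universe <- match.arg(gene_universe)
  for (p in c("max_fdr", "min_support", "min_confidence")) {
    v <- get(p)
    if (v <= 0 || v > 1) stop(p, " must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(beta) && beta < 1) stop("beta must be >= 1", call. = FALSE)
  if (edge_threshold <= 0 || edge_threshold >= 1) {
    stop("edge_threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  structure(list(counts = counts, metadata = metadata,
                 annotations = annotations, out_dir = out_dir,
                 contrast = contrast, min_count = min_count,
                 sample_frac = sample_frac, max_fdr = max_fdr,
                 min_fold = min_fold, beta = beta, powers = powers,
                 target_fit = target_fit,
                 min_module_size = min_module_size,
                 cut_height_quantile = cut_height_quantile,
                 merge_cut = merge_cut, min_kme = min_kme,
                 edge_threshold = edge_threshold,
                 min_degree = min_degree, hub_degree = hub_degree,
                 bins = bins, min_support = min_support,
                 min_confidence = min_confidence, min_lift = min_lift,
                 max_len = max_len, gene_universe = gene_universe,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — differential expression, co-expression
#' modules, network metrics, discretization, rule mining, function
#' prediction — writing each stage's artifact under `config$out_dir`
#' together with a machine-readable `manifest.json` (package version,
#' parameters, input checksum, per-stage record counts). A stage failure
#' aborts with the stage name in the error message. Given identical inputs
#' and configuration the outputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the stage results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- list()
  out <- function(f) file.path(config$out_dir, f)

  # -- stage 1: preprocessing and differential expression ------------------
  de <- .stage("preprocess_de", {
    filtered <- filter_low_counts(config$counts, config$min_count,
                                  config$sample_frac)
    sf <- size_factors(filtered)
    expr <- log2_expression(filtered, sf)
    res <- differential_expression(filtered, config$metadata,
                                   config$contrast)
    sel <- select_de_genes(res, config$max_fdr, config$min_fold)
    utils::write.csv(res, out("de_results.csv"), row.names = FALSE)
    writeLines(sel, out("de_genes.txt"))
    list(filtered = filtered, expr = expr, results = res, selected = sel)
  })
  records$preprocess_de <- nrow(de$results)

  # -- stage 2: co-expression modules --------------------------------------
  cx <- .stage("coexpression", {
    if (is.null(config$beta)) {
      pick <- pick_soft_threshold(de$expr, config$powers, config$target_fit)
      beta <- pick$beta
      utils::write.csv(pick$fit_table, out("beta_table.csv"),
                       row.names = FALSE)
    } else {
      beta <- config$beta
    }
    sim <- similarity_matrix(de$expr)
    adj <- adjacency_matrix(sim, beta)
    tom <- topological_overlap(adj)
    tree <- cluster_gene_tree(1 - tom)
    modules <- cut_modules(tree, config$min_module_size,
                           config$cut_height_quantile)
    if (any(modules$module > 0)) {
      modules <- merge_close_modules(de$expr[modules$gene_id, , drop = FALSE],
                                     modules, config$merge_cut)
      modules <- assign_by_membership(de$expr[modules$gene_id, , drop = FALSE],
                                      modules, config$min_kme)
      me <- module_eigengenes(de$expr[modules$gene_id, , drop = FALSE],
                              modules)
      utils::write.table(data.frame(sample_id = rownames(me), me,
                                    check.names = FALSE),
                         out("eigengenes.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    utils::write.table(modules, out("modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(beta = beta, tom = tom, modules = modules)
  })
  records$coexpression <- nrow(cx$modules)

  # -- stage 3: network metrics --------------------------------------------
  nw <- .stage("network_metrics", {
    in_module <- cx$modules$gene_id[cx$modules$module > 0]
    subset <- if (length(in_module) >= 2) in_module else NULL
    net <- build_network(cx$tom, config$edge_threshold, subset,
                         config$annotations)
    ct <- centrality_table(net)
    filtered_net <- filter_by_degree(net, config$min_degree)
    hubs <- hub_table(ct, config$hub_degree)
    utils::write.csv(ct, out("centrality.csv"), row.names = FALSE)
    utils::write.csv(hubs, out("hub_table.csv"), row.names = FALSE)
    export_edge_list(net, out("edge_list.tsv"))
    if (igraph::vcount(net) > 0) export_graphml(net, out("network.graphml"))
    list(net = net, filtered_net = filtered_net, centrality = ct,
         hubs = hubs)
  })
  records$network_metrics <- igraph::vcount(nw$net)

  # -- stage 4: discretization ---------------------------------------------
  dz <- .stage("discretize", {
    universe <- switch(config$gene_universe,
      network = igraph::V(nw$net)$name,
      modules = cx$modules$gene_id[cx$modules$module > 0],
      all = rownames(de$expr))
    if (length(universe) == 0) universe <- rownames(de$expr)
    bin <- discretize_matrix(de$expr[universe, , drop = FALSE], config$bins)
    utils::write.table(data.frame(sample_id = rownames(bin), bin,
                                  check.names = FALSE),
                       out("binary_matrix.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (config$bins == 2 && ncol(bin) > 0) {
      write_basket(bin, out("transactions.basket"))
    }
    bin
  })
  records$discretize <- ncol(dz)

  # -- stage 5: association rule mining ------------------------------------
  rl <- .stage("arm", {
    if (ncol(dz) == 0 || config$bins != 2) {
      rules <- generate_rules(apriori(matrix(FALSE, 1, 1,
        dimnames = list("t", "none")), 1), 1)[0, ]
    } else {
      freq <- apriori(dz, config$min_support, config$max_len)
      rules <- generate_rules(freq, config$min_confidence)
      rules <- filter_rules(rules, config$min_lift)
    }
    flat <- data.frame(
      rule_id = rules$rule_id,
      antecedent = vapply(rules$antecedent, paste, "", collapse = ";"),
      consequent = vapply(rules$consequent, paste, "", collapse = ";"),
      support = rules$support, confidence = rules$confidence,
      lift = rules$lift, rule_text = rules$rule_text,
      stringsAsFactors = FALSE)
    utils::write.csv(flat, out("rules.csv"), row.names = FALSE)
    rules
  })
  records$arm <- nrow(rl)

  # -- stage 6: function prediction ----------------------------------------
  pred <- NULL
  if (!is.null(config$annotations)) {
    pred <- .stage("prediction", {
      p <- predict_functions(rl, config$annotations)
      utils::write.csv(p, out("predictions.csv"), row.names = FALSE)
      p
    })
    records$prediction <- nrow(pred)
  }

  manifest <- list(
    package = "coexrules",
    version = as.character(utils::packageVersion("coexrules")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("counts", "metadata", "annotations",
                                  "out_dir"))],
    input = list(
      n_genes = nrow(config$counts), n_samples = ncol(config$counts),
      counts_md5 = .matrix_md5(config$counts)),
    selected_beta = cx$beta,
    stage_records = records)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(de = de, coexpression = cx, network = nw,
                 transactions = dz, rules = rl, predictions = pred,
                 manifest = manifest, out_dir = config$out_dir))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.matrix_md5 <- function(m) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(paste(colnames(m), collapse = "\t"),
               apply(m, 1, paste, collapse = "\t")), f)
  unname(tools::md5sum(f))
}
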