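# End-to-end orchestration of the multi-step method:
# preprocess (sex-adjust -> IQR filter -> log2) -> correlate -> select ->
# cluster-genes -> metagenes -> fit-tree -> evaluate.

#' Read a per-subject sex table
#' @param path CSV with columns `subject_id,sex`.
#' @return named character vector.
#' @export
read_sex <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("subject_id", "sex") %in% names(df)))
    stop("sex CSV needs columns subject_id, sex")
  setNames(df$sex, df$subject_id)
}

#' Run the full multi-step decision-tree pipeline
#'
#' Aligns the three tables on shared subjects, then runs: sex adjustment,
#' IQR filtering, log2 transform, gene-covariate Pearson screening with
#' Bonferroni control, complete-linkage gene clustering of
#' absolute-correlation profiles, per-cluster PCA metagenes, and an
#' information-gain decision tree supervised by confirmed asthma status,
#' evaluated by resubstitution and (optionally) bootstrap.
#'
#' @param expr an `expression_matrix` (intensity scale).
#' @param cov a `covariate_table`.
#' @param ind an `indicator_set`.
#' @param sex named per-subject sex vector.
#' @param config a `pipeline_config`.
#' @param bootstrap run the bootstrap evaluation (default `TRUE`).
#' @return list of stage outputs: `filtered_expr`, `correlation`,
#'   `selection`, `clusters`, `metagenes`, `tree`, `report`, `bootstrap`,
#'   and a `manifest` of per-stage counts.
#' @export
run_pipeline <- function(expr, cov, ind, sex, config = pipeline_config(),
                         bootstrap = TRUE) {
  al <- align_cohort(expr, cov, ind)
  expr <- al$expression; cov <- al$covariates; ind <- al$indicators

  adj <- adjust_for_sex(expr, sex)
  filt <- iqr_filter(adj, config$iqr_threshold)
  manifest <- list(n_subjects = length(expr$subject_ids),
                   n_subjects_dropped = al$n_dropped,
                   n_genes_in = length(expr$gene_ids),
                   n_genes_iqr = length(filt$kept_gene_ids))
  labels <- asthma_labels(ind)
  manifest$n_labeled <- length(labels)
  min_leaf <- effective_min_leaf(config, length(labels))
  manifest$min_leaf <- min_leaf

  empty_tree <- function() {
    counts <- table(factor(labels, levels = sort(unique(labels))))
    structure(list(root = list(type = "leaf", id = 1L,
                               counts = setNames(as.list(as.integer(counts)),
                                                 names(counts)),
                               majority = .majority_label(counts),
                               n = length(labels)),
                   n_subjects = length(labels), min_leaf = min_leaf,
                   gain_epsilon = config$gain_epsilon,
                   label_levels = sort(unique(labels)),
                   attribute_names = character(0),
                   subject_ids = names(labels)),
              class = "endotype_tree")
  }

  if (length(filt$kept_gene_ids) == 0) {
    tree <- empty_tree()
    scores <- matrix(0, length(labels), 0,
                     dimnames = list(names(labels), NULL))
    report <- evaluate_segregation(tree, scores, labels)
    manifest <- c(manifest, list(n_genes_selected = 0L, n_clusters = 0L,
                                 n_metagenes = 0L,
                                 n_leaves = 1L,
                                 overall_accuracy = report$overall_accuracy))
    return(list(filtered_expr = NULL, correlation = NULL, selection = NULL,
                clusters = NULL, metagenes = NULL, tree = tree,
                report = report, bootstrap = NULL, manifest = manifest,
                labels = labels, config = config))
  }

  lg <- log2_transform(filt$expr)
  corr <- correlate(lg, cov)
  m <- if (is.null(config$n_covariate_tests)) length(cov$covariate_ids)
       else config$n_covariate_tests
  alpha <- per_test_alpha(config$family_alpha, m)
  sel <- select_genes(corr, alpha)
  manifest$n_genes_selected <- length(sel$gene_ids)
  manifest$per_test_alpha <- alpha

  if (length(sel$gene_ids) == 0) {
    tree <- empty_tree()
    scores <- matrix(0, length(labels), 0,
                     dimnames = list(names(labels), NULL))
    report <- evaluate_segregation(tree, scores, labels)
    manifest <- c(manifest, list(n_clusters = 0L, n_metagenes = 0L,
                                 n_leaves = 1L,
                                 overall_accuracy = report$overall_accuracy))
    return(list(filtered_expr = lg, correlation = corr, selection = sel,
                clusters = NULL, metagenes = NULL, tree = tree,
                report = report, bootstrap = NULL, manifest = manifest,
                labels = labels, config = config))
  }

  k <- min(config$n_gene_clusters, length(sel$gene_ids))
  clusters <- cluster_genes(corr, k = k, gene_ids = sel$gene_ids)
  manifest$n_clusters <- k
  mg <- build_metagenes(lg, clusters, config$variance_fraction_min)
  manifest$n_metagenes <- length(mg$names)

  tree <- if (length(mg$names) == 0) empty_tree()
          else grow_tree(mg, labels, config)
  scores <- if (length(mg$names) == 0)
    matrix(0, length(labels), 0, dimnames = list(names(labels), NULL))
  else mg$scores
  report <- evaluate_segregation(tree, scores, labels)
  manifest$n_leaves <- tree_size(tree, leaves_only = TRUE)
  manifest$overall_accuracy <- report$overall_accuracy
  boot <- if (bootstrap && length(mg$names) > 0)
    bootstrap_evaluate(tree, mg$scores, labels, B = config$bootstrap_reps,
                       seed = config$rng_seed)
  else NULL

  list(filtered_expr = lg, correlation = corr, selection = sel,
       clusters = clusters, metagenes = mg, tree = tree, report = report,
       bootstrap = boot, manifest = manifest, labels = labels,
       config = config)
}

#' One-shot run with artifact output
#'
#' Executes [run_pipeline()] (optionally on a simulated cohort) and writes
#' every intermediate artifact plus a JSON run manifest (config snapshot,
#' seed, per-stage counts) to `out_dir`.
#'
#' @param expr_path,cov_path,ind_path,sex_path input file paths; ignored
#'   when `simulate` is `TRUE`.
#' @param out_dir output directory (created).
#' @param config a `pipeline_config`.
#' @param simulate simulate a default cohort instead of reading files.
#' @param sim_config a `synthetic_config` used when `simulate` is `TRUE`.
#' @param dictionary_path optional covariate dictionary CSV.
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_all <- function(expr_path = NULL, cov_path = NULL, ind_path = NULL,
                    sex_path = NULL, out_dir, config = pipeline_config(),
                    simulate = FALSE, sim_config = synthetic_config(),
                    dictionary_path = NULL) {
  if (simulate) {
    sim <- simulate_cohort(sim_config, seed = config$rng_seed)
    expr <- sim$expression; cov <- sim$covariates; ind <- sim$indicators
    sex <- sim$truth$sex
  } else {
    for (p in c(expr_path, cov_path, ind_path, sex_path))
      if (!file.exists(p)) stop("input file not found: ", p)
    expr <- read_expression(expr_path)
    cov <- read_covariates(cov_path, dictionary_path)
    ind <- read_indicators(ind_path)
    sex <- read_sex(sex_path)
  }
  res <- run_pipeline(expr, cov, ind, sex, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$filtered_expr))
    write_expression(res$filtered_expr, file.path(out_dir,
                                                  "expression_log2.tsv"))
  if (!is.null(res$correlation)) {
    utils::write.table(
      data.frame(covariate_id = rownames(res$correlation$r),
                 res$correlation$r, check.names = FALSE),
      file.path(out_dir, "correlations.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(res$selection$report,
                       file.path(out_dir, "selected_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$clusters))
    utils::write.table(
      data.frame(gene_id = names(res$clusters$labels),
                 cluster = unname(res$clusters$labels)),
      file.path(out_dir, "gene_clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  if (!is.null(res$metagenes)) write_metagenes(res$metagenes, out_dir)
  tree_to_json(res$tree, file.path(out_dir, "tree.json"))
  tree_to_dot(res$tree, file.path(out_dir, "tree.dot"))
  writeLines(format(res$tree), file.path(out_dir, "tree.txt"))
  utils::write.table(res$report$per_leaf,
                     file.path(out_dir, "segregation_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$bootstrap))
    utils::write.table(
      data.frame(statistic = c("mean", "sd", "p2.5", "p97.5"),
                 value = c(res$bootstrap$mean, res$bootstrap$sd,
                           res$bootstrap$ci)),
      file.path(out_dir, "bootstrap.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  manifest <- c(list(stages = c("preprocess", "correlate", "select",
                                "cluster-genes", "metagenes", "fit-tree",
                                "evaluate"),
                     seed = res$config$rng_seed,
                     config = unclass(res$config)),
                res$manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
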