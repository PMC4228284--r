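# Steps 1-2 of the multi-step method: Pearson screening of every
# (covariate, gene) pair with Bonferroni control, then complete-linkage
# clustering of the selected genes by their absolute-correlation profiles.

#' Bonferroni per-test alpha
#'
#' @param family_alpha family-wise error rate (e.g. 0.05).
#' @param m number of covariate tests (e.g. 81, giving 0.05/81 ~ 0.0006).
#' @return `family_alpha / m`.
#' @export
per_test_alpha <- function(family_alpha, m) {
  stopifnot(family_alpha > 0, family_alpha < 1)
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a positive integer")
  family_alpha / m
}

#' Correlate every covariate with every gene
#'
#' Pearson product-moment correlation of each covariate with each gene's
#' log2 expression over pairwise-complete subjects (missing covariate
#' values are dropped per pair; no imputation). Two-sided p-values come
#' from the exact t reference distribution,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom.
#' Zero-variance covariates or genes yield `r = 0`, `p = 1` with a warning.
#'
#' @param expr an `expression_matrix` with `scale_tag = "log2"`.
#' @param cov a `covariate_table` on the same subjects.
#' @return An object of class `correlation_result` with fields `r`, `p`
#'   (covariate x gene matrices), `n_used` (subjects per test), and
#'   `gene_ids`/`covariate_ids`.
#' @export
correlate <- function(expr, cov) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(cov, "covariate_table"))
  if (expr$scale_tag != "log2")
    stop("correlate expects a log2-scale expression matrix, got ",
         expr$scale_tag)
  if (!identical(sort(expr$subject_ids), sort(cov$subject_ids)))
    stop("expression and covariate tables must share the same subjects")
  X <- t(expr$values)[cov$subject_ids, , drop = FALSE]   # subject x gene
  C <- cov$values                                         # subject x covariate
  n_used <- crossprod(!is.na(C), matrix(1, nrow(X), ncol(X)))
  if (any(n_used < 3))
    stop("fewer than 3 pairwise-complete subjects for some test")
  r <- suppressWarnings(stats::cor(C, X, use = "pairwise.complete.obs"))
  degenerate <- is.na(r)
  if (any(degenerate)) {
    warning(sum(degenerate),
            " zero-variance covariate/gene pair(s); r set to 0, p to 1")
    r[degenerate] <- 0
  }
  r <- pmin(pmax(r, -1), 1)  # first argument keeps the dim attributes
  df <- n_used - 2
  tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  p[abs(r) >= 1] <- 0
  p[degenerate] <- 1
  dimnames(r) <- dimnames(p) <- dimnames(n_used) <-
    list(cov$covariate_ids, colnames(X))
  structure(list(r = r, p = p, n_used = n_used,
                 covariate_ids = cov$covariate_ids,
                 gene_ids = colnames(X)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %d covariates x %d genes\n",
              nrow(x$r), ncol(x$r)))
  invisible(x)
}

#' Select genes significantly associated with at least one covariate
#'
#' A gene is selected when its minimum p-value across covariates is below
#' the Bonferroni per-test alpha. The per-gene best covariate and its
#' `r`/`p` are reported for interpretation.
#'
#' @param corr a `correlation_result`.
#' @param alpha per-test alpha, typically [per_test_alpha()] of the family
#'   alpha and the number of covariates.
#' @return list with `gene_ids` (selected genes, original order),
#'   `per_test_alpha`, and `report` (data.frame: gene_id, best_covariate,
#'   r, p, selected).
#' @export
select_genes <- function(corr, alpha) {
  stopifnot(inherits(corr, "correlation_result"), alpha > 0, alpha <= 1)
  minp_idx <- apply(corr$p, 2, which.min)
  minp <- corr$p[cbind(minp_idx, seq_along(corr$gene_ids))]
  sel <- minp < alpha
  if (!any(sel)) message("select_genes: no gene passed alpha = ", alpha)
  report <- data.frame(
    gene_id = corr$gene_ids,
    best_covariate = corr$covariate_ids[minp_idx],
    r = corr$r[cbind(minp_idx, seq_along(corr$gene_ids))],
    p = minp,
    selected = sel,
    stringsAsFactors = FALSE
  )
  list(gene_ids = corr$gene_ids[sel], per_test_alpha = alpha, report = report)
}

# Spreadsheet-style cluster names: A..Z, AA, AB, ...
.cluster_names <- function(k) {
  nm <- character(k)
  for (i in seq_len(k)) {
    j <- i; s <- ""
    while (j > 0) { s <- paste0(LETTERS[(j - 1) %% 26 + 1], s)
                    j <- (j - 1) %/% 26 }
    nm[i] <- s
  }
  nm
}

#' Cluster genes by absolute-correlation profiles
#'
#' Each selected gene is represented by its vector of `|r|` across
#' covariates; genes are agglomerated by complete-linkage hierarchical
#' clustering of pairwise profile distances and the tree is cut to
#' exactly `k` clusters. Clusters are named "A", "B", ... in dendrogram
#' (left-to-right leaf) order. Genes are processed in lexicographic id
#' order so ties resolve deterministically.
#'
#' @param corr a `correlation_result`.
#' @param k number of clusters (default 11).
#' @param gene_ids genes to cluster (default: all genes in `corr`;
#'   normally the output of [select_genes()]).
#' @param metric profile distance: `"euclidean"` (default), `"manhattan"`,
#'   or `"correlation"` (1 - Pearson correlation between profiles).
#' @return An object of class `gene_cluster_set` with `labels` (named map
#'   gene id -> cluster name), `k`, `merge`/`height` (linkage record), and
#'   the `hclust` object.
#' @export
cluster_genes <- function(corr, k = 11, gene_ids = corr$gene_ids,
                          metric = c("euclidean", "manhattan",
                                     "correlation")) {
  stopifnot(inherits(corr, "correlation_result"))
  metric <- match.arg(metric)
  gene_ids <- sort(as.character(gene_ids))
  if (!all(gene_ids %in% corr$gene_ids))
    stop("gene_ids not present in the correlation result")
  if (k < 1 || k > length(gene_ids))
    stop("k must be between 1 and the number of selected genes (",
         length(gene_ids), ")")
  prof <- t(abs(corr$r[, gene_ids, drop = FALSE]))   # gene x covariate
  d <- switch(metric,
    euclidean = stats::dist(prof, method = "euclidean"),
    manhattan = stats::dist(prof, method = "manhattan"),
    correlation = stats::as.dist(1 - suppressWarnings(stats::cor(t(prof)))))
  if (anyNA(d)) d[is.na(d)] <- 0  # constant profiles under correlation metric
  hc <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(hc, k = k)
  # rename clusters in dendrogram leaf order
  leaf_order <- hc$order
  first_seen <- unique(raw[leaf_order])
  new_names <- setNames(.cluster_names(k), first_seen)
  labels <- setNames(new_names[as.character(raw)], names(raw))
  structure(list(labels = labels, k = as.integer(k),
                 merge = hc$merge, height = hc$height, hclust = hc,
                 metric = metric),
            class = "gene_cluster_set")
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("gene_cluster_set: %d genes in %d clusters (%s)\n",
              length(x$labels), x$k,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Mean silhouette over candidate cluster counts
#'
#' Guidance only (never auto-selected): mean silhouette width of the
#' complete-linkage gene clustering for each `k` in `k_range`.
#'
#' @param corr a `correlation_result`.
#' @param gene_ids genes to cluster.
#' @param k_range candidate cluster counts.
#' @inheritParams cluster_genes
#' @return data.frame with columns `k` and `mean_silhouette`.
#' @export
gene_cluster_k_guidance <- function(corr, gene_ids = corr$gene_ids,
                                    k_range = 2:20,
                                    metric = "euclidean") {
  gene_ids <- sort(as.character(gene_ids))
  prof <- t(abs(corr$r[, gene_ids, drop = FALSE]))
  k_range <- k_range[k_range >= 2 & k_range < length(gene_ids)]
  res <- vapply(k_range, function(k) {
    cl <- cluster_genes(corr, k = k, gene_ids = gene_ids, metric = metric)
    silhouette_index(prof, as.integer(factor(cl$labels[rownames(prof)])),
                     distance = "euclidean")
  }, numeric(1))
  data.frame(k = k_range, mean_silhouette = res)
}
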