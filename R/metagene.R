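# Step 3: per-cluster PCA metagenes. Each gene cluster's centered
# expression block is decomposed by SVD; every principal component
# explaining at least `variance_fraction_min` of the cluster's variance
# becomes a metagene (a subject-wise PC score vector).

#' Build metagenes from gene clusters
#'
#' For each gene cluster, genes are centered (per-gene mean subtracted; no
#' unit-variance scaling, since log2 expression is already on a common
#' scale) and the subject-wise principal components of the cluster block
#' are computed by singular value decomposition. Components explaining at
#' least `variance_fraction_min` of the cluster variance are retained and
#' named `"<cluster>-<component>"` (e.g. `"F-2"` for the second PC of
#' cluster F). Sign convention: each loading vector's largest-magnitude
#' element is positive, so runs are reproducible.
#'
#' A single-gene cluster yields one metagene equal to the centered gene
#' (variance fraction 1).
#'
#' @param expr an `expression_matrix` with `scale_tag = "log2"`.
#' @param clusters a `gene_cluster_set` over genes present in `expr`.
#' @param variance_fraction_min minimum variance fraction (default 0.05).
#' @param scale. if `TRUE`, also scale genes to unit variance
#'   (sensitivity analysis only; default `FALSE`).
#' @return An object of class `metagene_set`: `scores` (subject x
#'   metagene matrix, zero-mean columns), `loadings` (list of unit-norm
#'   named vectors over member genes), `centers` (per-metagene named
#'   vector of gene means used for centering), `variance_fraction`,
#'   `cluster_of`, `names`.
#' @export
build_metagenes <- function(expr, clusters, variance_fraction_min = 0.05,
                            scale. = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(clusters, "gene_cluster_set"),
            variance_fraction_min > 0, variance_fraction_min < 1)
  if (expr$scale_tag != "log2")
    stop("build_metagenes expects a log2-scale matrix, got ", expr$scale_tag)
  genes <- names(clusters$labels)
  miss <- setdiff(genes, expr$gene_ids)
  if (length(miss))
    stop("clustered gene(s) absent from expression matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (length(expr$subject_ids) < 2) stop("need >=2 subjects")
  cluster_ids <- unique(clusters$labels[order(names(clusters$labels))])
  cluster_ids <- sort(cluster_ids)
  scores <- list(); loadings <- list(); centers <- list()
  varfrac <- numeric(0); cluster_of <- character(0); nms <- character(0)
  retained_per_cluster <- setNames(integer(length(cluster_ids)), cluster_ids)
  for (cl in cluster_ids) {
    members <- sort(names(clusters$labels)[clusters$labels == cl])
    X <- expr$values[members, , drop = FALSE]          # gene x subject
    mu <- rowMeans(X)
    Xc <- X - mu
    if (scale.) {
      sds <- apply(X, 1, stats::sd)
      sds[sds == 0] <- 1
      Xc <- Xc / sds
    }
    sv <- svd(Xc)
    total <- sum(sv$d^2)
    if (total <= 0) {
      # constant cluster: one degenerate metagene of zeros
      vf <- 1
      keep <- 1L
      sv$d <- c(1, rep(0, length(sv$d) - 1))
      sv$u <- matrix(0, nrow(Xc), length(sv$d)); sv$u[1, 1] <- 1
      sv$v <- matrix(0, ncol(Xc), length(sv$d))
    } else vf <- sv$d^2 / total
    keep <- which(vf >= variance_fraction_min)
    retained_per_cluster[cl] <- length(keep)
    for (j in keep) {
      load <- sv$u[, j]
      names(load) <- members
      sgn <- sign(load[which.max(abs(load))])
      if (sgn == 0) sgn <- 1
      sc <- sv$v[, j] * sv$d[j] * sgn
      nm <- paste0(cl, "-", which(keep == j))
      nms <- c(nms, nm)
      loadings[[nm]] <- load * sgn
      centers[[nm]] <- mu
      scores[[nm]] <- setNames(sc, expr$subject_ids)
      varfrac <- c(varfrac, vf[j])
      cluster_of <- c(cluster_of, cl)
    }
  }
  if (length(scores)) {
    S <- do.call(cbind, scores)
  } else {
    S <- matrix(numeric(0), nrow = length(expr$subject_ids), ncol = 0,
                dimnames = list(expr$subject_ids, NULL))
  }
  colnames(S) <- nms
  names(varfrac) <- names(cluster_of) <- nms
  structure(list(scores = S, loadings = loadings, centers = centers,
                 variance_fraction = varfrac, cluster_of = cluster_of,
                 names = nms, subject_ids = expr$subject_ids,
                 variance_fraction_min = variance_fraction_min,
                 retained_per_cluster = retained_per_cluster),
            class = "metagene_set")
}

#' @export
print.metagene_set <- function(x, ...) {
  cat(sprintf("metagene_set: %d metagenes over %d subjects (per cluster: %s)\n",
              length(x$names), length(x$subject_ids),
              paste(names(x$retained_per_cluster), x$retained_per_cluster,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Project new subjects onto fitted metagenes
#'
#' Applies the stored per-gene centering means and loadings to a new
#' expression matrix. Projecting the training matrix reproduces the
#' training scores.
#'
#' @param metagenes a `metagene_set`.
#' @param expr_new an `expression_matrix` (log2 scale) containing every
#'   member gene of every metagene.
#' @return matrix of scores, new subjects x metagenes.
#' @export
project_metagenes <- function(metagenes, expr_new) {
  stopifnot(inherits(metagenes, "metagene_set"),
            inherits(expr_new, "expression_matrix"))
  out <- matrix(NA_real_, length(expr_new$subject_ids),
                length(metagenes$names),
                dimnames = list(expr_new$subject_ids, metagenes$names))
  for (nm in metagenes$names) {
    genes <- names(metagenes$loadings[[nm]])
    miss <- setdiff(genes, expr_new$gene_ids)
    if (length(miss))
      stop("metagene ", nm, " member gene(s) missing: ",
           paste(miss, collapse = ", "))
    Xc <- expr_new$values[genes, , drop = FALSE] - metagenes$centers[[nm]]
    out[, nm] <- drop(crossprod(Xc, metagenes$loadings[[nm]]))
  }
  out
}

#' Write metagene scores, loadings, and variance report
#' @param metagenes a `metagene_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metagenes <- function(metagenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- data.frame(subject_id = metagenes$subject_ids, metagenes$scores,
                   check.names = FALSE)
  utils::write.table(sc, file.path(dir, "metagene_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ld <- do.call(rbind, lapply(metagenes$names, function(nm)
    data.frame(gene_id = names(metagenes$loadings[[nm]]), metagene = nm,
               weight = unname(metagenes$loadings[[nm]]))))
  utils::write.table(ld, file.path(dir, "metagene_loadings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vr <- data.frame(metagene = metagenes$names,
                   cluster = unname(metagenes$cluster_of),
                   variance_fraction = unname(metagenes$variance_fraction))
  utils::write.table(vr, file.path(dir, "metagene_variance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
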