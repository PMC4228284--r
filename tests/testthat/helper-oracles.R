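# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, exhaustive enumeration) so they remain
# independent of the implementation paths they check.

oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# max gain over all n-1 candidate midpoints, honoring min_leaf
oracle_best_split <- function(scores, labels, min_leaf) {
  s <- sort(unique(scores))
  best <- NULL
  h <- oracle_entropy(table(labels))
  n <- length(scores)
  if (length(s) < 2) return(NULL)
  for (i in seq_len(length(s) - 1)) {
    thr <- (s[i] + s[i + 1]) / 2
    left <- scores <= thr
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    gain <- h - (sum(left) / n) * oracle_entropy(table(labels[left])) -
      (sum(!left) / n) * oracle_entropy(table(labels[!left]))
    if (is.null(best) || gain > best$gain + 1e-12)
      best <- list(threshold = thr, gain = gain)
  }
  best
}

oracle_silhouette <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (cl in unique(labels)) {
      if (cl == labels[i]) next
      b <- min(b, mean(D[i, labels == cl]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_gamma <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  within <- c(); between <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) within <- c(within, D[i, j])
    else between <- c(between, D[i, j])
  }
  sp <- 0; sm <- 0
  for (w in within) for (b in between) {
    if (w < b) sp <- sp + 1
    if (w > b) sm <- sm + 1
  }
  if (sp + sm == 0) 0 else (sp - sm) / (sp + sm)
}

oracle_c_index <- function(D, labels) {
  D <- as.matrix(D)
  n <- nrow(D)
  dd <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dd <- c(dd, D[i, j])
    if (labels[i] == labels[j]) within <- c(within, D[i, j])
  }
  l <- length(within)
  S <- sum(within)
  smin <- sum(sort(dd)[1:l])
  smax <- sum(sort(dd, decreasing = TRUE)[1:l])
  if (smax == smin) 0 else (S - smin) / (smax - smin)
}

# plain Lloyd iteration with fixed initial centers (rows of `centers`)
oracle_lloyd <- function(X, centers, max_iter = 100) {
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (k in seq_len(nrow(centers)))
      if (any(assign == k))
        new_centers[k, ] <- colMeans(X[assign == k, , drop = FALSE])
    if (all(abs(new_centers - centers) < 1e-12)) break
    centers <- new_centers
  }
  assign
}

# quantile-bin oracle: sort and slice into n_levels equal-count groups,
# matching the type-7 + ties-to-lower-bin convention via direct comparison
oracle_quantile_bins <- function(values, n_levels) {
  cuts <- quantile(values, seq_len(n_levels - 1) / n_levels, type = 7,
                   names = FALSE)
  sapply(values, function(x) sum(x > cuts))
}

# ---- fixture builders ----------------------------------------------------

make_expr <- function(values, scale_tag = "intensity",
                      gene_ids = sprintf("g%02d", seq_len(nrow(values))),
                      subject_ids = sprintf("S%02d", seq_len(ncol(values)))) {
  expression_matrix(values, gene_ids, subject_ids, scale_tag)
}

make_cov <- function(values, categories = NULL,
                     subject_ids = sprintf("S%02d", seq_len(nrow(values))),
                     covariate_ids = sprintf("c%02d", seq_len(ncol(values)))) {
  rownames(values) <- subject_ids
  colnames(values) <- covariate_ids
  covariate_table(values, categories = categories)
}

table1_roster <- function() {
  read.csv(system.file("extdata", "table1_covariates.csv",
                       package = "endotree"), colClasses = "character")
}

small_cohort <- function(seed = 42, n_subjects = 80, n_genes = 200, ...) {
  simulate_cohort(synthetic_config(n_subjects = n_subjects,
                                   n_known_status = n_subjects,
                                   n_genes = n_genes, ...), seed = seed)
}
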