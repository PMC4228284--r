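# Comparison baselines: gene-wise two-sample t-tests, single-domain
# clustering scored by three internal validity indices over a
# distance x method x k grid, and the weighted Modk-prototypes
# mixed-domain clustering with prototype-z-score biomarker flagging.

#' Gene-wise two-sample t-tests
#'
#' Classic pooled-variance two-sample t-test per gene (Welch by flag),
#' two-sided, comparing expression between the two label groups. Flags
#' at `alpha` uncorrected and Bonferroni-corrected across genes.
#' A degenerate gene (zero pooled variance) gets `p = 1` with a warning
#' unless the group means differ exactly, in which case `p = 0`.
#'
#' @param expr an `expression_matrix` (log2 scale expected).
#' @param labels named binary labels over a subset of subjects.
#' @param alpha per-gene significance level (default 0.05).
#' @param welch use Welch's unequal-variance statistic.
#' @return data.frame: gene_id, t, df, p, significant,
#'   significant_bonferroni.
#' @export
gene_ttests <- function(expr, labels, alpha = 0.05, welch = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(names(labels))) stop("labels must be named by subject id")
  subj <- intersect(expr$subject_ids, names(labels))
  y <- factor(as.character(labels[subj]))
  if (nlevels(y) != 2) stop("labels must have exactly two groups")
  if (any(table(y) < 2)) stop("need >=2 subjects per group")
  X <- expr$values[, subj, drop = FALSE]
  i1 <- y == levels(y)[1]; i2 <- !i1
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(X[, i1, drop = FALSE]); m2 <- rowMeans(X[, i2, drop = FALSE])
  v1 <- apply(X[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(X[, i2, drop = FALSE], 1, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0 | !is.finite(tstat)
  if (any(degen)) {
    warning(sum(degen), " gene(s) with degenerate variance; p set to 1")
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    tstat[degen] <- 0
  }
  m <- length(p)
  data.frame(gene_id = expr$gene_ids, t = tstat, df = df, p = p,
             significant = p < alpha,
             significant_bonferroni = p < alpha / m,
             stringsAsFactors = FALSE)
}

# ---- distances -----------------------------------------------------------

.scan_distances <- c("euclidean", "manhattan", "chebyshev", "canberra",
                     "bray_curtis", "squared_euclidean")

#' Pairwise distance matrix for the clustering baselines
#' @param X numeric matrix, points in rows.
#' @param distance one of euclidean, manhattan, chebyshev, canberra,
#'   bray_curtis, squared_euclidean.
#' @return a `dist` object.
#' @export
pair_dist <- function(X, distance = .scan_distances) {
  distance <- match.arg(distance)
  X <- as.matrix(X)
  switch(distance,
    euclidean = stats::dist(X, "euclidean"),
    manhattan = stats::dist(X, "manhattan"),
    chebyshev = stats::dist(X, "maximum"),
    canberra = stats::dist(X, "canberra"),
    squared_euclidean = stats::dist(X, "euclidean")^2,
    bray_curtis = {
      n <- nrow(X)
      out <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        num <- sum(abs(X[i, ] - X[j, ]))
        den <- sum(abs(X[i, ] + X[j, ]))
        out[i, j] <- out[j, i] <- if (den == 0) 0 else num / den
      }
      stats::as.dist(out)
    })
}

# ---- internal cluster validity indices ----------------------------------

#' Mean silhouette width
#'
#' For each point, `s = (b - a) / max(a, b)` with `a` the mean distance to
#' its own cluster's other members and `b` the smallest mean distance to
#' another cluster. Singleton clusters and degenerate `a = b = 0` points
#' score 0 by convention.
#'
#' @param X numeric matrix (points in rows) or a `dist` object.
#' @param labels cluster assignment (>= 2 clusters).
#' @param distance distance name used when `X` is a matrix.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_index <- function(X, labels, distance = "euclidean") {
  D <- if (inherits(X, "dist")) as.matrix(X)
       else as.matrix(pair_dist(X, distance))
  labels <- as.vector(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 clusters")
  n <- nrow(D)
  stopifnot(length(labels) == n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Baker-Hubert Gamma index
#'
#' Goodman-Kruskal rank correlation between "same cluster" and distance:
#' over all (within-pair, between-pair) comparisons,
#' `Gamma = (s_plus - s_minus) / (s_plus + s_minus)`, where `s_plus`
#' counts within-distance < between-distance and `s_minus` the reverse;
#' ties count for neither, and 0/0 gives 0.
#'
#' @inheritParams silhouette_index
#' @return Gamma in `[-1, 1]`.
#' @export
gamma_index <- function(X, labels, distance = "euclidean") {
  d <- if (inherits(X, "dist")) X else pair_dist(X, distance)
  labels <- as.vector(labels)
  within <- .within_pair_mask(labels)
  dw <- as.vector(d)[within]; db <- as.vector(d)[!within]
  if (!length(dw) || !length(db))
    stop("need at least one within-cluster and one between-cluster pair")
  sb <- sort(db)
  # for each within distance: count of between distances strictly greater/less
  n_gt <- length(db) - findInterval(dw, sb)                 # db >  dw
  n_lt <- findInterval(dw, sb, left.open = TRUE)            # db <  dw
  s_plus <- sum(n_gt); s_minus <- sum(n_lt)
  if (s_plus + s_minus == 0) return(0)
  (s_plus - s_minus) / (s_plus + s_minus)
}

#' Hubert-Levine C index
#'
#' `C = (S - S_min) / (S_max - S_min)` where `S` is the sum of
#' within-cluster pairwise distances and `S_min`/`S_max` are the sums of
#' the `l` smallest/largest pairwise distances overall (`l` = number of
#' within-cluster pairs). Smaller is better; `S_max = S_min` gives 0.
#'
#' @inheritParams silhouette_index
#' @return C in `[0, 1]`.
#' @export
c_index <- function(X, labels, distance = "euclidean") {
  d <- if (inherits(X, "dist")) X else pair_dist(X, distance)
  labels <- as.vector(labels)
  within <- .within_pair_mask(labels)
  l <- sum(within)
  if (l == 0) stop("need at least one within-cluster pair")
  dv <- as.vector(d)
  S <- sum(dv[within])
  sorted <- sort(dv)
  S_min <- sum(sorted[seq_len(l)])
  S_max <- sum(sorted[seq.int(length(dv) - l + 1, length(dv))])
  if (S_max == S_min) return(0)
  (S - S_min) / (S_max - S_min)
}

# logical vector over dist-vector order marking within-cluster pairs
.within_pair_mask <- function(labels) {
  n <- length(labels)
  same <- outer(labels, labels, "==")
  same[lower.tri(same)]  # column-major lower triangle == dist vector order
}

# ---- validity scan -------------------------------------------------------

.scan_methods <- c("kmeans", "pam", "hier_single", "hier_complete",
                   "hier_average", "hier_ward")

#' Grid search over distance, clustering method, and cluster count
#'
#' Clusters the rows of `X` for every (distance, method, k) combination
#' and scores each partition with all three internal validity indices.
#' Infeasible combinations (kmeans or Ward linkage with a non-Euclidean
#' distance) are skipped and logged in the `skipped` attribute. The best
#' rows are the argmax of silhouette and Gamma and the argmin of the
#' C index.
#'
#' @param X numeric matrix, points (subjects or genes) in rows.
#' @param domain_tag label recorded in the output (e.g. "expression").
#' @param distances subset of the supported distances.
#' @param methods subset of kmeans, pam, hier_single, hier_complete,
#'   hier_average, hier_ward. `pam` (partitioning around medoids) is a
#'   compact medoid-based reimplementation operating on the distance
#'   matrix.
#' @param k_range candidate cluster counts within `[2, n - 1]`.
#' @param seed RNG seed for kmeans/pam restarts.
#' @return An object of class `validity_scan`: data.frame of scored rows
#'   plus a `best` attribute (one row per index).
#' @export
validity_scan <- function(X, domain_tag = "data",
                          distances = c("euclidean", "manhattan"),
                          methods = c("kmeans", "hier_complete",
                                      "hier_average"),
                          k_range = 2:10, seed = 1L) {
  X <- as.matrix(X)
  distances <- match.arg(distances, .scan_distances, several.ok = TRUE)
  methods <- match.arg(methods, .scan_methods, several.ok = TRUE)
  n <- nrow(X)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range must contain values in [2, n-1]")
  rows <- list(); skipped <- character(0)
  for (dist_name in distances) {
    d <- pair_dist(X, dist_name)
    for (method in methods) {
      if (method %in% c("kmeans", "hier_ward") && dist_name != "euclidean") {
        skipped <- c(skipped, paste(dist_name, method, sep = "+"))
        next
      }
      for (k in k_range) {
        lab <- switch(method,
          kmeans = withr_seed(seed, stats::kmeans(X, centers = k,
                                                  nstart = 5)$cluster),
          pam = .pam_medoids(d, k, seed),
          hier_single = stats::cutree(stats::hclust(d, "single"), k),
          hier_complete = stats::cutree(stats::hclust(d, "complete"), k),
          hier_average = stats::cutree(stats::hclust(d, "average"), k),
          hier_ward = stats::cutree(stats::hclust(d, "ward.D2"), k))
        if (length(unique(lab)) < 2) next
        rows[[length(rows) + 1]] <- data.frame(
          domain = domain_tag, distance = dist_name, method = method, k = k,
          silhouette = silhouette_index(d, lab),
          gamma = gamma_index(d, lab),
          c_index = c_index(d, lab),
          stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  best <- rbind(
    cbind(index = "silhouette", grid[which.max(grid$silhouette), ]),
    cbind(index = "gamma", grid[which.max(grid$gamma), ]),
    cbind(index = "c_index", grid[which.min(grid$c_index), ]))
  rownames(best) <- NULL
  structure(grid, best = best, skipped = skipped, class = c("validity_scan",
                                                            "data.frame"))
}

# Small PAM: BUILD-style greedy medoid seeding then swap phase on the
# distance matrix. Adequate for the scan's modest problem sizes.
.pam_medoids <- function(d, k, seed = 1L) {
  D <- as.matrix(d)
  n <- nrow(D)
  medoids <- integer(0)
  cost <- function(med) sum(apply(D[, med, drop = FALSE], 1, min))
  for (i in seq_len(k)) {
    cand <- setdiff(seq_len(n), medoids)
    costs <- vapply(cand, function(m) cost(c(medoids, m)), numeric(1))
    medoids <- c(medoids, cand[which.min(costs)])
  }
  repeat {
    improved <- FALSE
    base <- cost(medoids)
    for (mi in seq_along(medoids)) {
      for (o in setdiff(seq_len(n), medoids)) {
        trial <- medoids; trial[mi] <- o
        if (cost(trial) < base - 1e-12) {
          medoids <- trial; base <- cost(medoids); improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  apply(D[, medoids, drop = FALSE], 1, which.min)
}

# ---- Modk-prototypes -----------------------------------------------------

#' Modk-prototypes configuration
#'
#' Weights are (expression, clinical, indicator) fractions summing to 1,
#' or `"adaptive"`. The preset schemes mirror the published weighting
#' table: 33/33/33, 20/40/40, 40/20/40, 50/50/0, 30/60/10, 60/30/10,
#' 40/40/20, plus adaptive.
#'
#' @param k number of clusters (>= 2).
#' @param weights numeric length-3 non-negative weights (renormalized to
#'   sum to 1) or the string `"adaptive"`.
#' @param max_iter maximum alternation iterations.
#' @param n_starts random restarts; the best final objective wins.
#' @param rng_seed integer seed.
#' @return An object of class `modk_config`.
#' @export
modk_config <- function(k = 8, weights = c(1, 1, 1) / 3, max_iter = 100,
                        n_starts = 10, rng_seed = 1L) {
  stopifnot(k >= 2, max_iter >= 1, n_starts >= 1)
  adaptive <- identical(weights, "adaptive")
  if (!adaptive) {
    stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  structure(list(k = as.integer(k), weights = if (adaptive) NULL else weights,
                 adaptive = adaptive, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts),
                 rng_seed = as.integer(rng_seed)),
            class = "modk_config")
}

#' Preset Modk weighting schemes
#' @return named list of weight vectors (fractions) plus `"adaptive"`.
#' @export
modk_weighting_schemes <- function() {
  list("33/33/33" = c(1, 1, 1) / 3,
       "20/40/40" = c(0.2, 0.4, 0.4),
       "40/20/40" = c(0.4, 0.2, 0.4),
       "50/50/0" = c(0.5, 0.5, 0),
       "30/60/10" = c(0.3, 0.6, 0.1),
       "60/30/10" = c(0.6, 0.3, 0.1),
       "40/40/20" = c(0.4, 0.4, 0.2),
       "Adaptive" = "adaptive")
}

.zscore_cols <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  sweep(sweep(M, 2, mu), 2, sd, "/")
}

#' Fit the Modk-prototypes mixed-domain clustering
#'
#' k-prototypes alternation over three data domains: the per-subject cost
#' to a cluster prototype is
#' `w_e * d2_expr + w_c * d2_clin + w_i * d_match`, squared Euclidean for
#' the two numeric blocks (z-scored per variable first so domains are
#' commensurate) and simple matching (count of disagreeing attributes)
#' for the categorical indicator block. The update step sets numeric
#' prototypes to cluster means and categorical prototypes to cluster
#' modes. At fixed weights the objective is non-increasing; in adaptive
#' mode weights are recomputed each iteration as
#' `w_d proportional to 1 / (1 + within-cluster cost_d)` (renormalized),
#' so more compact domains gain weight. Empty clusters are re-seeded with
#' the subject farthest from its prototype. Best of `n_starts` restarts
#' by final objective.
#'
#' @param expr_block numeric matrix, subjects x genes.
#' @param clinical_block numeric matrix, subjects x covariates (complete;
#'   impute first).
#' @param indicator_block data.frame/matrix of categorical values,
#'   subjects x indicators.
#' @param config a `modk_config`.
#' @return An object of class `modk_result`: `assignment` (named),
#'   `prototypes` (list with `expression`, `clinical`, `indicator`),
#'   `objective_trace`, `weight_trace`, `weights`, `objective`.
#' @export
modk_fit <- function(expr_block, clinical_block, indicator_block, config) {
  stopifnot(inherits(config, "modk_config"))
  E <- as.matrix(expr_block)
  Cl <- as.matrix(clinical_block)
  Ind <- as.matrix(as.data.frame(indicator_block, stringsAsFactors = FALSE))
  storage.mode(Ind) <- "character"
  n <- nrow(E)
  if (nrow(Cl) != n || nrow(Ind) != n)
    stop("blocks must share subjects (same row count)")
  if (anyNA(Cl)) stop("clinical block has missing values; impute first")
  if (config$k > n) stop("k exceeds the number of subjects")
  subj <- rownames(E)
  if (is.null(subj)) subj <- as.character(seq_len(n))
  Ez <- .zscore_cols(E); Clz <- .zscore_cols(Cl)
  k <- config$k
  run_one <- function() {
    centers <- sample.int(n, k)
    protoE <- Ez[centers, , drop = FALSE]
    protoC <- Clz[centers, , drop = FALSE]
    protoI <- Ind[centers, , drop = FALSE]
    w <- if (config$adaptive) c(1, 1, 1) / 3 else config$weights
    assign_prev <- rep(0L, n)
    obj_trace <- numeric(0); w_trace <- list()
    for (iter in seq_len(config$max_iter)) {
      dE <- .sq_dist_to(Ez, protoE)
      dC <- .sq_dist_to(Clz, protoC)
      dI <- .match_dist_to(Ind, protoI)
      cost <- w[1] * dE + w[2] * dC + w[3] * dI
      assign <- max.col(-cost, ties.method = "first")
      # re-seed empty clusters with the subject farthest from its prototype
      for (cl in which(tabulate(assign, k) == 0)) {
        worst <- which.max(cost[cbind(seq_len(n), assign)])
        assign[worst] <- cl
        cost[worst, ] <- Inf; cost[worst, cl] <- 0
      }
      for (cl in seq_len(k)) {
        ix <- which(assign == cl)
        protoE[cl, ] <- colMeans(Ez[ix, , drop = FALSE])
        protoC[cl, ] <- colMeans(Clz[ix, , drop = FALSE])
        protoI[cl, ] <- apply(Ind[ix, , drop = FALSE], 2, .mode_value)
      }
      dE <- .sq_dist_to(Ez, protoE); dC <- .sq_dist_to(Clz, protoC)
      dI <- .match_dist_to(Ind, protoI)
      pick <- cbind(seq_len(n), assign)
      within <- c(sum(dE[pick]), sum(dC[pick]), sum(dI[pick]))
      obj_trace <- c(obj_trace, sum(w * within))
      w_trace[[iter]] <- w
      if (identical(assign, assign_prev)) break
      assign_prev <- assign
      if (config$adaptive) {
        w <- 1 / (1 + within)
        w <- w / sum(w)
      }
    }
    list(assignment = setNames(assign, subj),
         prototypes = list(expression = protoE, clinical = protoC,
                           indicator = protoI),
         objective_trace = obj_trace,
         weight_trace = do.call(rbind, w_trace),
         weights = w, objective = obj_trace[length(obj_trace)])
  }
  best <- withr_seed(config$rng_seed, {
    fits <- lapply(seq_len(config$n_starts), function(s) run_one())
    fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  })
  best$config <- config
  best$blocks <- list(expression = E, clinical = Cl, indicator = Ind)
  class(best) <- "modk_result"
  best
}

# squared Euclidean distances of every row of X to every row of P
.sq_dist_to <- function(X, P) {
  xx <- rowSums(X^2)
  pp <- rowSums(P^2)
  pmax(outer(xx, pp, "+") - 2 * X %*% t(P), 0)
}

# simple matching: number of disagreeing categorical attributes
.match_dist_to <- function(X, P) {
  out <- matrix(0, nrow(X), nrow(P))
  for (j in seq_len(ncol(X)))
    out <- out + outer(X[, j], P[, j], "!=")
  out
}

.mode_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]
}

#' @export
print.modk_result <- function(x, ...) {
  cat(sprintf("modk_result: k=%d, objective %.4f after %d iteration(s)\n",
              x$config$k, x$objective, length(x$objective_trace)))
  print(table(x$assignment))
  invisible(x)
}

#' Flag per-cluster biomarkers from Modk prototypes
#'
#' Prototypes are standardized to z-scores against each variable's overall
#' mean and standard deviation across subjects. A clinical covariate is
#' flagged for a cluster when `|z| > clinical_sd_threshold` (default 1);
#' a gene is flagged when `|z|` exceeds the two-sided standard-normal
#' quantile for `gene_alpha` (1.96 at 0.05). Zero-variance variables are
#' excluded with a warning.
#'
#' @param result a `modk_result`.
#' @param clinical_sd_threshold z threshold for clinical covariates.
#' @param gene_alpha two-sided alpha defining the gene z threshold.
#' @return list with `clinical` and `genes`: data.frames of
#'   (cluster, variable, z).
#' @export
modk_biomarkers <- function(result, clinical_sd_threshold = 1.0,
                            gene_alpha = 0.05) {
  stopifnot(inherits(result, "modk_result"))
  zthr_gene <- stats::qnorm(1 - gene_alpha / 2)
  flag_block <- function(block, proto, thr) {
    mu <- colMeans(block)
    sd <- apply(block, 2, stats::sd)
    keep <- sd > 0 & !is.na(sd)
    if (any(!keep))
      warning(sum(!keep), " zero-variance variable(s) excluded from flagging")
    rows <- list()
    for (cl in seq_len(nrow(proto))) {
      z <- (proto[cl, keep] - mu[keep]) / sd[keep]
      hit <- abs(z) > thr
      if (any(hit))
        rows[[length(rows) + 1]] <- data.frame(
          cluster = cl, variable = colnames(block)[keep][hit],
          z = unname(z[hit]), stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(cluster = integer(0), variable = character(0),
                    z = numeric(0))
  }
  # prototypes live on the z-scored scale; express them on the raw scale
  unz <- function(proto, block) {
    mu <- colMeans(block); sd <- apply(block, 2, stats::sd)
    sd[sd == 0 | is.na(sd)] <- 1
    sweep(sweep(proto, 2, sd, "*"), 2, mu, "+")
  }
  list(clinical = flag_block(result$blocks$clinical,
                             unz(result$prototypes$clinical,
                                 result$blocks$clinical),
                             clinical_sd_threshold),
       genes = flag_block(result$blocks$expression,
                          unz(result$prototypes$expression,
                              result$blocks$expression),
                          zthr_gene))
}

#' Segregation accuracy of a Modk clustering
#'
#' Clusters are labeled by majority vote of the supplied binary labels
#' (ties to `non_asthmatic`); overall and per-cluster accuracy follow the
#' same definitions as [evaluate_segregation()].
#'
#' @param result a `modk_result`.
#' @param labels named binary labels.
#' @return A `segregation_report`.
#' @export
modk_accuracy <- function(result, labels) {
  stopifnot(inherits(result, "modk_result"))
  if (is.null(names(labels))) stop("labels must be named by subject id")
  subj <- intersect(names(result$assignment), names(labels))
  if (!length(subj)) stop("no labeled subjects in the clustering")
  cl <- result$assignment[subj]
  y <- as.character(labels[subj])
  per_leaf <- do.call(rbind, lapply(split(seq_along(subj), cl), function(ix) {
    counts <- table(factor(y[ix], levels = sort(unique(y))))
    maj <- .majority_label(counts)
    data.frame(leaf_id = cl[ix[1]], majority = maj, n = length(ix),
               pct_correct = 100 * mean(y[ix] == maj))
  }))
  per_leaf <- per_leaf[order(per_leaf$leaf_id), , drop = FALSE]
  rownames(per_leaf) <- NULL
  overall <- 100 * sum(per_leaf$n * per_leaf$pct_correct / 100) / length(subj)
  grp <- table(factor(per_leaf$majority,
                      levels = c("asthmatic", "non_asthmatic")))
  structure(list(overall_accuracy = overall,
                 group_counts = c(n_asthmatic_leaves = unname(grp["asthmatic"]),
                                  n_non_asthmatic_leaves =
                                    unname(grp["non_asthmatic"])),
                 per_leaf = per_leaf, n_subjects = length(subj)),
            class = "segregation_report")
}

#' Per-subject binary calls implied by a clustering or tree report
#'
#' Maps each subject to its cluster/leaf majority label; used for
#' inter-method agreement.
#'
#' @param assignment named cluster/leaf id per subject.
#' @param labels named binary labels (majority computed from these).
#' @return named character vector of calls.
#' @export
majority_calls <- function(assignment, labels) {
  subj <- intersect(names(assignment), names(labels))
  cl <- assignment[subj]; y <- as.character(labels[subj])
  maj <- vapply(split(y, cl), function(v)
    .majority_label(table(factor(v, levels = sort(unique(y))))), character(1))
  setNames(maj[as.character(cl)], subj)
}
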