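test_that("gene t-tests match the hand pooled-t computation", {
  # (1,2,3) vs (4,5,6): pooled s2 = 1, t = -3 / sqrt(2/3) ~ -3.674, df 4
  expr <- make_expr(rbind(c(1, 2, 3, 4, 5, 6)), scale_tag = "log2")
  y <- setNames(rep(c("asthmatic", "non_asthmatic"), each = 3),
                expr$subject_ids)
  res <- gene_ttests(expr, y)
  want <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, want$t, tolerance = 1e-12)
  expect_equal(res$p, want$p, tolerance = 1e-12)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)
})

test_that("gene t-tests match the oracle on random fixtures", {
  set.seed(83)
  X <- matrix(rnorm(20 * 12), 20, 12)
  expr <- make_expr(X, scale_tag = "log2")
  y <- setNames(rep(c("asthmatic", "non_asthmatic"), each = 6),
                expr$subject_ids)
  res <- gene_ttests(expr, y)
  for (g in 1:20) {
    want <- oracle_pooled_t(X[g, 1:6], X[g, 7:12])
    expect_equal(res$t[g], want$t, tolerance = 1e-10)
    expect_equal(res$p[g], want$p, tolerance = 1e-10)
  }
  # identical samples -> t = 0, p = 1
  eq <- make_expr(matrix(rep(c(1, 2, 3), 2), nrow = 1), scale_tag = "log2")
  y2 <- setNames(rep(c("asthmatic", "non_asthmatic"), each = 3),
                 eq$subject_ids)
  res2 <- suppressWarnings(gene_ttests(eq, y2))
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
})

test_that("uncorrected lists from different noisy labelings barely overlap", {
  set.seed(89)
  X <- matrix(rnorm(400 * 40), 400, 40)
  expr <- make_expr(X, scale_tag = "log2")
  y1 <- setNames(sample(rep(c("asthmatic", "non_asthmatic"), 20)),
                 expr$subject_ids)
  y2 <- setNames(sample(rep(c("asthmatic", "non_asthmatic"), 20)),
                 expr$subject_ids)
  l1 <- gene_ttests(expr, y1)$significant
  l2 <- gene_ttests(expr, y2)$significant
  overlap <- sum(l1 & l2)
  expect_lt(overlap, 0.25 * max(sum(l1), sum(l2), 1) + 2)
})

test_that("silhouette matches the hand example and brute-force oracle", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c(1, 1, 2, 2)
  s <- silhouette_index(X, labels)
  expect_equal(s, (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-12)
  expect_equal(round(s, 4), 0.8997)
  expect_equal(silhouette_index(matrix(rep(1, 4), ncol = 1), labels), 0)
  expect_error(silhouette_index(X, rep(1, 4)), ">= 2 clusters")
  set.seed(97)
  for (rep in 1:5) {
    Y <- matrix(rnorm(24), 8, 3)
    lb <- sample(1:3, 8, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(silhouette_index(Y, lb),
                 oracle_silhouette(dist(Y), lb), tolerance = 1e-12)
  }
})

test_that("gamma and C index match exhaustive double-loop oracles", {
  # perfectly separated clusters
  X <- matrix(c(0, 0.2, 10, 10.2), ncol = 1)
  expect_equal(gamma_index(X, c(1, 1, 2, 2)), 1)
  expect_equal(c_index(X, c(1, 1, 2, 2)), 0)
  # all pairwise distances equal (regular simplex in 3D)
  S <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_equal(gamma_index(S, c(1, 1, 2, 2)), 0)
  expect_equal(c_index(S, c(1, 1, 2, 2)), 0)
  # pathological clustering grouping the farthest points -> C near 1
  Xp <- matrix(c(0, 1, 100, 101), ncol = 1)
  expect_equal(c_index(Xp, c(1, 2, 2, 1)),
               oracle_c_index(dist(Xp), c(1, 2, 2, 1)), tolerance = 1e-12)
  expect_gt(c_index(Xp, c(1, 2, 2, 1)), 0.95)
  set.seed(101)
  for (rep in 1:10) {
    Y <- matrix(rnorm(18), 6, 3)
    lb <- sample(1:2, 6, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(gamma_index(Y, lb), oracle_gamma(dist(Y), lb),
                 tolerance = 1e-12)
    expect_equal(c_index(Y, lb), oracle_c_index(dist(Y), lb),
                 tolerance = 1e-12)
  }
})

test_that("validity indices are invariant to point order and relabeling", {
  set.seed(103)
  X <- matrix(rnorm(30), 10, 3)
  lb <- rep(1:2, 5)
  perm <- sample(10)
  relab <- c(2, 1)[lb]
  for (f in list(silhouette_index, gamma_index, c_index)) {
    expect_equal(f(X, lb), f(X[perm, ], lb[perm]), tolerance = 1e-12)
    expect_equal(f(X, lb), f(X, relab), tolerance = 1e-12)
  }
})

test_that("validity scan scores the full grid and finds k = 2 blobs", {
  set.seed(107)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  scan <- validity_scan(X, "toy", distances = c("euclidean", "manhattan"),
                        methods = c("hier_complete", "hier_average"),
                        k_range = 2:4)
  expect_equal(nrow(scan), 2 * 2 * 3)
  best <- attr(scan, "best")
  expect_equal(best$k[best$index == "silhouette"], 2)
  expect_equal(best$k[best$index == "gamma"], 2)
  expect_equal(best$k[best$index == "c_index"], 2)
  # single blob: silhouette stays well below the separated-blob score
  X1 <- matrix(rnorm(200), 100, 2)
  scan1 <- validity_scan(X1, "blob", distances = "euclidean",
                         methods = "hier_complete", k_range = 2:5)
  expect_true(all(scan1$silhouette < 0.45))
  expect_lt(max(scan1$silhouette),
            max(scan$silhouette[scan$method == "hier_complete"]))
  # infeasible combos skipped
  scan2 <- validity_scan(X, "toy", distances = "manhattan",
                         methods = c("kmeans", "hier_single"), k_range = 2)
  expect_match(attr(scan2, "skipped"), "manhattan\\+kmeans")
  expect_equal(unique(scan2$method), "hier_single")
})

test_that("modk with pure expression weights reproduces Lloyd k-means", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 5), 20, 3))
    rownames(X) <- sprintf("S%02d", 1:40)
    Cl <- matrix(rnorm(40), 40, 1)
    Ind <- data.frame(flag = sample(c("yes", "no"), 40, TRUE))
    cfg <- modk_config(k = 2, weights = c(1, 0, 0), n_starts = 1,
                       rng_seed = seed)
    fit <- modk_fit(X, Cl, Ind, cfg)
    # oracle: Lloyd iteration from the same initial centers on the
    # z-scored expression block
    Xz <- scale(X)
    init <- withr::with_seed(seed, sample.int(40, 2))
    want <- oracle_lloyd(Xz, Xz[init, , drop = FALSE])
    expect_equal(unname(adjusted_rand_index(fit$assignment, want)), 1)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
  }
})

test_that("modk degenerate cases behave", {
  # indicator-only weights with two distinct patterns -> perfect split
  Ind <- data.frame(a = rep(c("x", "y"), each = 2),
                    b = rep(c("p", "q"), each = 2))
  X <- matrix(rnorm(8), 4, 2); Cl <- matrix(rnorm(4), 4, 1)
  rownames(X) <- sprintf("S%d", 1:4)
  fit <- modk_fit(X, Cl, Ind, modk_config(k = 2, weights = c(0, 0, 1),
                                          n_starts = 5, rng_seed = 1))
  expect_equal(fit$objective, 0)
  expect_length(unique(fit$assignment[1:2]), 1)
  expect_length(unique(fit$assignment[3:4]), 1)
  # k = number of distinct subjects -> objective 0
  X2 <- matrix(c(0, 5, 10, 0, 5, 10), 3, 2); rownames(X2) <- c("a", "b", "c")
  fit2 <- modk_fit(X2, matrix(0, 3, 1), data.frame(z = c("u", "v", "w")),
                   modk_config(k = 3, weights = c(1, 0, 1), n_starts = 5,
                               rng_seed = 2))
  expect_equal(fit2$objective, 0, tolerance = 1e-12)
  expect_error(modk_fit(X2, matrix(0, 3, 1), data.frame(z = c("u", "v", "w")),
                        modk_config(k = 4)), "exceeds")
})

test_that("adaptive weighting renormalizes and keeps a trace", {
  set.seed(109)
  X <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(40, 4), 10, 4))
  rownames(X) <- sprintf("S%02d", 1:20)
  Cl <- matrix(rnorm(40), 20, 2)
  Ind <- data.frame(f = sample(c("y", "n"), 20, TRUE))
  fit <- modk_fit(X, Cl, Ind, modk_config(k = 2, weights = "adaptive",
                                          n_starts = 2, rng_seed = 3))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(nrow(fit$weight_trace) >= 1)
})

test_that("biomarker flagging applies the 1-sd and 1.96-z thresholds", {
  set.seed(113)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("S%02d", 1:n),
                                                  sprintf("g%d", 1:5)))
  Cl <- matrix(rnorm(n * 3), n, 3, dimnames = list(rownames(X),
                                                   sprintf("c%d", 1:3)))
  # a minority cluster (6 of 40) shifted hard so its prototype sits far
  # from the overall mean relative to the overall (mixture) sd: the gene
  # needs |z| > 1.96, the clinical covariate only |z| > 1 (a minority
  # fraction p bounds the attainable prototype z at sqrt((1-p)/p))
  Cl[1:6, 1] <- Cl[1:6, 1] + 6
  X[1:6, 1] <- X[1:6, 1] + 20
  Ind <- data.frame(f = rep(c("y", "n"), each = 20))
  fit <- modk_fit(X, Cl, Ind, modk_config(k = 2, weights = c(0.5, 0.5, 0),
                                          n_starts = 10, rng_seed = 4))
  fl <- modk_biomarkers(fit)
  expect_true("c1" %in% fl$clinical$variable)
  expect_true("g1" %in% fl$genes$variable)
  expect_true(all(abs(fl$clinical$z) > 1))
  expect_true(all(abs(fl$genes$z) > qnorm(0.975)))
  # identical prototypes (k clusters of identical data) flag nothing
  same <- matrix(1:2, 4, 2, byrow = TRUE,
                 dimnames = list(sprintf("S%d", 1:4), c("a", "b")))
  fit2 <- suppressWarnings(
    modk_fit(same, same, data.frame(z = rep("u", 4)),
             modk_config(k = 2, n_starts = 2, rng_seed = 5)))
  fl2 <- suppressWarnings(modk_biomarkers(fit2))
  expect_equal(nrow(fl2$clinical), 0)
})

test_that("modk accuracy report mirrors the segregation definitions", {
  assignment <- setNames(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2),
                         sprintf("S%02d", 1:12))
  y <- setNames(c(rep("asthmatic", 6), rep("non_asthmatic", 4),
                  "asthmatic", "asthmatic"), names(assignment))
  fit <- structure(list(assignment = assignment), class = "modk_result")
  rep <- modk_accuracy(fit, y)
  c1 <- rep$per_leaf[rep$per_leaf$leaf_id == 1, ]
  expect_equal(c1$pct_correct, 60)
  expect_equal(rep$overall_accuracy, 100 * 8 / 12, tolerance = 1e-10)
  # pure clusters -> 100%
  y_pure <- setNames(c(rep("asthmatic", 10), rep("non_asthmatic", 2)),
                     names(assignment))
  expect_equal(modk_accuracy(fit, y_pure)$overall_accuracy, 100)
  calls <- majority_calls(assignment, y)
  expect_equal(unname(calls["S01"]), "asthmatic")
  expect_equal(agreement(calls, y), 100 * 8 / 12)
})
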