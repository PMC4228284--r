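make_corr_fixture <- function(expr_vals, cov_vals) {
  expr <- make_expr(expr_vals, scale_tag = "log2")
  cov <- make_cov(cov_vals)
  correlate(expr, cov)
}

test_that("per_test_alpha is the Bonferroni quotient", {
  expect_equal(signif(per_test_alpha(0.05, 81), 1), 6e-4)  # printed as 0.0006
  expect_equal(per_test_alpha(0.05, 1), 0.05)
  expect_equal(per_test_alpha(0.10, 4), 0.025)
  expect_error(per_test_alpha(0.05, 0))
})

test_that("correlate matches hand and two-loop oracles", {
  # hand example: r = 10 / sqrt(10 * 14.8)
  ev <- matrix(c(2, 1, 4, 3, 6), nrow = 1)
  cv <- matrix(1:5, ncol = 1)
  corr <- make_corr_fixture(ev, cv)
  expect_equal(corr$r[1, 1], 10 / sqrt(10 * 14.8), tolerance = 1e-12)

  # p-value via the exact t transform: r = 0.5, n = 30 -> p ~ 0.005
  tstat <- 0.5 * sqrt(28) / sqrt(1 - 0.25)
  expect_equal(round(2 * pt(-tstat, 28), 3), 0.005)

  # self-correlation
  x <- rnorm(8)
  corr2 <- make_corr_fixture(matrix(x, nrow = 1), matrix(x, ncol = 1))
  expect_equal(corr2$r[1, 1], 1)
  expect_equal(corr2$p[1, 1], 0)

  # oracle equivalence on a random 20-subject x 10-gene x 4-covariate
  # fixture with scattered missing covariate cells (pairwise deletion)
  set.seed(31)
  E <- matrix(rnorm(200), 10, 20)
  C <- matrix(rnorm(80), 20, 4)
  C[sample(80, 6)] <- NA
  corr3 <- make_corr_fixture(E, C)
  for (ci in 1:4) for (gi in 1:10)
    expect_equal(corr3$r[ci, gi], oracle_pearson(C[, ci], E[gi, ]),
                 tolerance = 1e-12)
})

test_that("degenerate tests get r = 0, p = 1 with a warning", {
  E <- matrix(c(1, 2, 3, 4, 5, 5, 5, 5), 2, 4, byrow = TRUE)
  C <- matrix(c(1, 3, 2, 8, 2, 2, 2, 2), 4, 2)
  expect_warning(corr <- make_corr_fixture(E, C), "zero-variance")
  expect_equal(corr$r[2, 2], 0)
  expect_equal(corr$p[2, 2], 1)
  expect_true(abs(corr$r[1, 1]) > 0)
})

test_that("correlation, selection, and clustering are permutation invariant", {
  set.seed(17)
  E <- matrix(rnorm(120), 6, 20)
  C <- matrix(rnorm(60), 20, 3)
  corr_a <- make_corr_fixture(E, C)
  perm <- sample(20)
  expr_b <- expression_matrix(E[, perm, drop = FALSE],
                              sprintf("g%02d", 1:6),
                              sprintf("S%02d", (1:20))[perm],
                              scale_tag = "log2")
  cov_b <- covariate_table(C[perm, , drop = FALSE],
                           sprintf("S%02d", (1:20))[perm],
                           sprintf("c%02d", 1:3))
  corr_b <- correlate(expr_b, cov_b)
  expect_equal(corr_b$r, corr_a$r, tolerance = 1e-12)
  expect_equal(select_genes(corr_b, 0.05)$gene_ids,
               select_genes(corr_a, 0.05)$gene_ids)
  cl_a <- cluster_genes(corr_a, k = 3)
  cl_b <- cluster_genes(corr_b, k = 3)
  expect_identical(cl_a$labels, cl_b$labels)
})

test_that("gene selection applies the min-p rule and is monotone in alpha", {
  set.seed(23)
  n <- 50
  cov_sig <- rnorm(n)
  E <- rbind(0.9 * cov_sig + 0.1 * rnorm(n),   # r ~ 0.9 -> p << 0.0006
             rnorm(n))                          # noise
  corr <- make_corr_fixture(E, cbind(cov_sig, rnorm(n)))
  sel <- select_genes(corr, per_test_alpha(0.05, 81))
  expect_true("g01" %in% sel$gene_ids)
  expect_equal(sel$report$best_covariate[1], "c01")

  # pure-noise genes at n = 146 stay unselected at the Bonferroni threshold
  set.seed(29)
  En <- matrix(rnorm(146 * 5), 5, 146)
  Cn <- matrix(rnorm(146 * 3), 146, 3)
  corr_n <- make_corr_fixture(En, Cn)
  expect_length(select_genes(corr_n, per_test_alpha(0.05, 81))$gene_ids, 0)

  # monotone: larger alpha selects a superset; alpha = 1 selects all
  alphas <- c(1e-6, 1e-3, 0.05, 1)
  sels <- lapply(alphas, function(a) select_genes(corr, a)$gene_ids)
  for (i in seq_len(length(sels) - 1))
    expect_true(all(sels[[i]] %in% sels[[i + 1]]))
  expect_length(sels[[4]], 2)
})

test_that("complete-linkage clustering recovers planted profile blocks", {
  # 6 genes: three correlate with covariates {c1,c2}, three with {c3,c4}
  set.seed(41)
  n <- 60
  c1 <- rnorm(n); c2 <- rnorm(n); c3 <- rnorm(n); c4 <- rnorm(n)
  E <- rbind(c1 + c2 + 0.3 * rnorm(n), c1 + c2 + 0.3 * rnorm(n),
             c1 + c2 + 0.3 * rnorm(n), c3 + c4 + 0.3 * rnorm(n),
             c3 + c4 + 0.3 * rnorm(n), c3 + c4 + 0.3 * rnorm(n))
  corr <- make_corr_fixture(E, cbind(c1, c2, c3, c4))
  cl <- cluster_genes(corr, k = 2)
  expect_length(unique(cl$labels[c("g01", "g02", "g03")]), 1)
  expect_length(unique(cl$labels[c("g04", "g05", "g06")]), 1)
  expect_false(cl$labels[["g01"]] == cl$labels[["g04"]])
  # brute-force check: between-block profile distances exceed within-block
  prof <- t(abs(corr$r))
  d <- as.matrix(dist(prof))
  within <- c(d[1, 2], d[1, 3], d[2, 3], d[4, 5], d[4, 6], d[5, 6])
  between <- d[1:3, 4:6]
  expect_true(min(between) > max(within))

  # identical profiles merge at height 0 and always share a cluster
  E2 <- rbind(E, E[1, ])
  corr2 <- make_corr_fixture(E2, cbind(c1, c2, c3, c4))
  for (k in 2:6) {
    cl2 <- cluster_genes(corr2, k = k)
    expect_identical(cl2$labels[["g01"]], cl2$labels[["g07"]])
  }
  # k = number of genes -> singletons; k too large -> error
  cl_n <- cluster_genes(corr, k = 6)
  expect_length(unique(cl_n$labels), 6)
  expect_error(cluster_genes(corr, k = 7), "between 1 and")
})

test_that("cluster names follow dendrogram order and heights are monotone", {
  set.seed(43)
  E <- matrix(rnorm(8 * 30), 8, 30)
  corr <- make_corr_fixture(E, matrix(rnorm(90), 30, 3))
  cl <- cluster_genes(corr, k = 4)
  expect_setequal(unique(cl$labels), c("A", "B", "C", "D"))
  # first cluster encountered along the dendrogram leaves is "A"
  leaves <- cl$hclust$labels[cl$hclust$order]
  expect_identical(unname(cl$labels[leaves[1]]), "A")
  expect_true(all(diff(cl$height) >= -1e-12))
})
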