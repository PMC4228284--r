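# Step 4: greedy information-gain decision tree over metagene scores.
# Plain information gain (not gain ratio), no post-pruning; the only
# regularizers are the minimum-leaf-size constraint and a small gain
# epsilon operationalizing "splits no longer improve information gain".
# Split rule: left = score <= threshold, right = score > threshold.
# Ties among equal-gain splits: smaller threshold, then lexicographically
# first metagene name, so fits are deterministic.

#' Shannon entropy of label counts, in bits
#' @param counts non-negative label counts, not all zero.
#' @return entropy in bits, with `0 * log(0) = 0`.
#' @export
entropy <- function(counts) {
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative and not all zero")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of a threshold split
#'
#' `H(labels) - sum_side (n_side / n) * H(labels_side)` for the partition
#' `score <= threshold` vs `score > threshold`.
#'
#' @param scores per-subject numeric attribute values.
#' @param labels per-subject class labels.
#' @param threshold split point; both sides must be non-empty.
#' @return information gain in bits.
#' @export
info_gain <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  left <- scores <= threshold
  if (!any(left) || all(left)) stop("both sides of the split must be non-empty")
  h <- entropy(table(labels))
  nl <- sum(left); n <- length(scores)
  h - (nl / n) * entropy(table(labels[left])) -
    ((n - nl) / n) * entropy(table(labels[!left]))
}

#' Best admissible threshold split of one attribute
#'
#' Evaluates candidate thresholds at midpoints between consecutive
#' distinct sorted score values, restricted to splits leaving at least
#' `min_leaf` subjects on each side, and returns the maximum-gain
#' threshold (ties: smaller threshold). Returns `NULL` when no admissible
#' split has gain above `gain_epsilon`.
#'
#' @param scores,labels per-subject values and class labels.
#' @param min_leaf minimum subjects on each side.
#' @param gain_epsilon minimum acceptable gain in bits.
#' @return list(threshold, gain) or `NULL`.
#' @export
best_split <- function(scores, labels, min_leaf, gain_epsilon = 1e-6) {
  n <- length(scores)
  stopifnot(length(labels) == n, min_leaf >= 1)
  if (n < 2 * min_leaf) return(NULL)
  ord <- order(scores)
  s <- scores[ord]
  y <- factor(labels[ord])
  counts <- table(y)
  h_parent <- entropy(counts)
  if (h_parent == 0) return(NULL)
  # cumulative class counts after each sorted position
  onehot <- stats::model.matrix(~ y - 1)
  cum <- apply(onehot, 2, cumsum)
  best <- NULL
  # candidate cut after position i (1-based), i.e. between s[i] and s[i+1]
  for (i in seq_len(n - 1)) {
    if (s[i] == s[i + 1]) next
    if (i < min_leaf || n - i < min_leaf) next
    left_counts <- cum[i, ]
    right_counts <- counts - left_counts
    gain <- h_parent - (i / n) * entropy(left_counts) -
      ((n - i) / n) * entropy(right_counts)
    thr <- (s[i] + s[i + 1]) / 2
    if (gain > gain_epsilon &&
        (is.null(best) || gain > best$gain + 1e-12 ||
         (abs(gain - best$gain) <= 1e-12 && thr < best$threshold)))
      best <- list(threshold = thr, gain = gain)
  }
  best
}

#' Grow an information-gain decision tree over metagene scores
#'
#' Greedy recursive partitioning: at each node the (metagene, threshold)
#' pair maximizing information gain is chosen among splits leaving at
#' least `min_leaf` subjects per side; growth stops when a node is pure,
#' too small, or no admissible split gains more than `gain_epsilon` bits.
#' Only subjects with a known label are used.
#'
#' @param metagenes a `metagene_set`, or a numeric subject x attribute
#'   score matrix with dimnames.
#' @param labels named binary labels (`asthmatic`/`non_asthmatic`); names
#'   are subject ids present in the score matrix.
#' @param config a `pipeline_config` (supplies `gain_epsilon` and, via
#'   [effective_min_leaf()], the leaf-size constraint).
#' @return An object of class `endotype_tree`: nested `root` node plus
#'   training metadata.
#' @export
grow_tree <- function(metagenes, labels, config = pipeline_config()) {
  S <- if (inherits(metagenes, "metagene_set")) metagenes$scores
       else as.matrix(metagenes)
  if (is.null(names(labels)))
    stop("labels must be named by subject id")
  subj <- intersect(rownames(S), names(labels))
  if (!length(subj)) stop("no labeled subjects present in the score matrix")
  S <- S[subj, , drop = FALSE]
  y <- as.character(labels[subj])
  min_leaf <- effective_min_leaf(config, length(subj))
  eps <- config$gain_epsilon
  label_levels <- sort(unique(y))
  leaf_counter <- new.env()
  leaf_counter$n <- 0L
  mk_leaf <- function(idx) {
    leaf_counter$n <- leaf_counter$n + 1L
    counts <- table(factor(y[idx], levels = label_levels))
    list(type = "leaf", id = leaf_counter$n,
         counts = as.list(as.integer(counts)) |>
           setNames(label_levels),
         majority = .majority_label(counts),
         n = length(idx))
  }
  build <- function(idx) {
    if (length(unique(y[idx])) <= 1 || length(idx) < 2 * min_leaf)
      return(mk_leaf(idx))
    best <- NULL
    for (m in sort(colnames(S))) {
      cand <- best_split(S[idx, m], y[idx], min_leaf, eps)
      if (is.null(cand)) next
      if (is.null(best) || cand$gain > best$gain + 1e-12 ||
          (abs(cand$gain - best$gain) <= 1e-12 &&
           (cand$threshold < best$threshold - 1e-12 ||
            (abs(cand$threshold - best$threshold) <= 1e-12 &&
             m < best$metagene))))
        best <- list(metagene = m, threshold = cand$threshold,
                     gain = cand$gain)
    }
    if (is.null(best)) return(mk_leaf(idx))
    left <- idx[S[idx, best$metagene] <= best$threshold]
    right <- setdiff(idx, left)
    list(type = "split", metagene = best$metagene,
         threshold = best$threshold, gain = best$gain,
         left = build(left), right = build(right))
  }
  root <- build(seq_along(subj))
  structure(list(root = root, n_subjects = length(subj),
                 min_leaf = min_leaf, gain_epsilon = eps,
                 label_levels = label_levels,
                 attribute_names = colnames(S),
                 subject_ids = subj),
            class = "endotype_tree")
}

# tie -> non_asthmatic (the conservative call); for other label alphabets,
# the lexicographically later level, which "non_asthmatic" happens to be.
.majority_label <- function(counts) {
  mx <- which(counts == max(counts))
  nm <- names(counts)[mx]
  if ("non_asthmatic" %in% nm) "non_asthmatic" else nm[length(nm)]
}

#' Route subjects through a fitted tree
#'
#' @param tree an `endotype_tree`.
#' @param scores subject x attribute score matrix (or `metagene_set`).
#' @return data.frame with `subject_id`, `leaf_id`, `predicted` (the
#'   leaf's training majority label).
#' @export
predict_tree <- function(tree, scores) {
  S <- if (inherits(scores, "metagene_set")) scores$scores
       else as.matrix(scores)
  route <- function(node, x) {
    while (node$type == "split") {
      node <- if (x[[node$metagene]] <= node$threshold) node$left
              else node$right
    }
    node
  }
  leaves <- apply(S, 1, function(x) route(tree$root, x), simplify = FALSE)
  data.frame(subject_id = rownames(S),
             leaf_id = vapply(leaves, `[[`, integer(1), "id"),
             predicted = vapply(leaves, `[[`, character(1), "majority"),
             stringsAsFactors = FALSE)
}

#' Segregation accuracy report for a fitted tree
#'
#' Routes each labeled subject to its leaf; leaf label = training majority
#' vote (ties go to `non_asthmatic`). Reports overall accuracy
#' (sum over leaves of the max class count / n, as a percentage), the
#' number of asthmatic- vs non-asthmatic-majority leaves, and per-leaf
#' percent correct.
#'
#' @param tree an `endotype_tree`.
#' @param scores score matrix or `metagene_set`.
#' @param labels named binary labels.
#' @return An object of class `segregation_report`.
#' @export
evaluate_segregation <- function(tree, scores, labels) {
  S <- if (inherits(scores, "metagene_set")) scores$scores
       else as.matrix(scores)
  subj <- intersect(rownames(S), names(labels))
  if (!length(subj)) stop("no labeled subjects to evaluate")
  pred <- predict_tree(tree, S[subj, , drop = FALSE])
  y <- as.character(labels[subj])
  per_leaf <- do.call(rbind, lapply(split(seq_along(subj), pred$leaf_id),
    function(ix) {
      maj <- pred$predicted[ix[1]]
      data.frame(leaf_id = pred$leaf_id[ix[1]], majority = maj,
                 n = length(ix),
                 pct_correct = 100 * mean(y[ix] == maj))
    }))
  per_leaf <- per_leaf[order(per_leaf$leaf_id), , drop = FALSE]
  rownames(per_leaf) <- NULL
  overall <- 100 * mean(pred$predicted == y)
  grp <- table(factor(per_leaf$majority,
                      levels = c("asthmatic", "non_asthmatic")))
  structure(list(overall_accuracy = overall,
                 group_counts = c(n_asthmatic_leaves = unname(grp["asthmatic"]),
                                  n_non_asthmatic_leaves =
                                    unname(grp["non_asthmatic"])),
                 per_leaf = per_leaf,
                 n_subjects = length(subj)),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf("segregation_report: overall %.1f%% (%d subjects), leaves %d asthmatic / %d non-asthmatic\n",
              x$overall_accuracy, x$n_subjects,
              x$group_counts[["n_asthmatic_leaves"]],
              x$group_counts[["n_non_asthmatic_leaves"]]))
  print(x$per_leaf, row.names = FALSE)
  invisible(x)
}

#' Bootstrap evaluation of a fixed tree
#'
#' Draws `B` subject-level resamples with replacement, routes each through
#' the fixed fitted tree (no refitting), and records the accuracy of the
#' leaf-majority predictions against the resampled labels. Summarized by
#' mean, sd, and 2.5/97.5 percentiles.
#'
#' @param tree an `endotype_tree`.
#' @param scores score matrix or `metagene_set`.
#' @param labels named binary labels.
#' @param B number of bootstrap resamples (default 10000).
#' @param seed RNG seed for reproducibility.
#' @return list with `mean`, `sd`, `ci` (2.5/97.5 percentiles), and the
#'   per-resample `accuracies`.
#' @export
bootstrap_evaluate <- function(tree, scores, labels, B = 10000, seed = 1L) {
  stopifnot(B >= 1)
  S <- if (inherits(scores, "metagene_set")) scores$scores
       else as.matrix(scores)
  subj <- intersect(rownames(S), names(labels))
  pred <- predict_tree(tree, S[subj, , drop = FALSE])
  correct <- pred$predicted == as.character(labels[subj])
  n <- length(subj)
  acc <- withr_seed(seed, {
    vapply(seq_len(B), function(b) mean(correct[sample.int(n, n,
                                                           replace = TRUE)]),
           numeric(1))
  })
  list(mean = mean(acc), sd = stats::sd(acc),
       ci = stats::quantile(acc, c(0.025, 0.975), names = TRUE),
       accuracies = acc)
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Percent agreement between two binary assignments
#' @param assign_a,assign_b named per-subject calls over the same subjects.
#' @return percentage of subjects with identical calls.
#' @export
agreement <- function(assign_a, assign_b) {
  if (is.null(names(assign_a)) || is.null(names(assign_b)))
    stop("assignments must be named by subject id")
  shared <- intersect(names(assign_a), names(assign_b))
  if (!length(shared)) stop("assignments share no subjects")
  100 * mean(assign_a[shared] == assign_b[shared])
}

# ---- tree export ---------------------------------------------------------

#' Export a fitted tree as JSON
#' @param tree an `endotype_tree`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "endotype_tree"))
  json <- jsonlite::toJSON(unclass(tree), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' Read a fitted tree back from JSON
#' @param path JSON file path (or a JSON string).
#' @return An `endotype_tree` with identical predictions to the exported
#'   tree.
#' @export
tree_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  fix <- function(node) {
    if (is.null(node$type)) stop("malformed tree JSON: node without type")
    if (node$type == "split") {
      if (is.null(node$metagene) || is.null(node$threshold) ||
          is.null(node$left) || is.null(node$right))
        stop("malformed tree JSON: incomplete internal node")
      node$left <- fix(node$left); node$right <- fix(node$right)
    } else {
      node$id <- as.integer(node$id)
      node$counts <- lapply(node$counts, as.integer)
    }
    node
  }
  x$root <- fix(x$root)
  x$min_leaf <- as.integer(x$min_leaf)
  x$n_subjects <- as.integer(x$n_subjects)
  x$label_levels <- as.character(x$label_levels)
  structure(x, class = "endotype_tree")
}

#' Export a fitted tree in Graphviz DOT format
#' @param tree an `endotype_tree`.
#' @param path optional output file.
#' @return DOT source as a character string.
#' @export
tree_to_dot <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "endotype_tree"))
  lines <- c("digraph endotype_tree {", "  node [shape=box];")
  counter <- new.env(); counter$i <- 0L
  emit <- function(node) {
    counter$i <- counter$i + 1L
    me <- paste0("n", counter$i)
    if (node$type == "split") {
      lines <<- c(lines, sprintf("  %s [label=\"%s <= %.4g\"];", me,
                                 node$metagene, node$threshold))
      l <- emit(node$left); r <- emit(node$right)
      lines <<- c(lines, sprintf("  %s -> %s [label=\"yes\"];", me, l),
                  sprintf("  %s -> %s [label=\"no\"];", me, r))
    } else {
      cts <- paste(names(node$counts), unlist(node$counts), sep = "=",
                   collapse = ", ")
      lines <<- c(lines, sprintf(
        "  %s [label=\"leaf %d: %s\\n(%s)\" shape=ellipse];",
        me, node$id, node$majority, cts))
    }
    me
  }
  emit(tree$root)
  lines <- c(lines, "}")
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(out, path)
  out
}

#' @export
format.endotype_tree <- function(x, ...) {
  fmt <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "split") {
      c(sprintf("%sif %s <= %.6g:", pad, node$metagene, node$threshold),
        fmt(node$left, indent + 1),
        sprintf("%selse:  # %s > %.6g", pad, node$metagene, node$threshold),
        fmt(node$right, indent + 1))
    } else {
      cts <- paste(names(node$counts), unlist(node$counts), sep = "=",
                   collapse = ", ")
      sprintf("%sleaf %d -> %s (%s)", pad, node$id, node$majority, cts)
    }
  }
  paste(fmt(x$root, 0), collapse = "\n")
}

#' @export
print.endotype_tree <- function(x, ...) {
  cat(sprintf("endotype_tree: %d training subjects, min_leaf %d\n",
              x$n_subjects, x$min_leaf))
  cat(format(x), "\n")
  invisible(x)
}

#' Number of nodes in a fitted tree
#' @param tree an `endotype_tree`.
#' @param leaves_only count only terminal leaves.
#' @return integer node count.
#' @export
tree_size <- function(tree, leaves_only = FALSE) {
  count <- function(node) {
    if (node$type == "leaf") return(1L)
    (if (leaves_only) 0L else 1L) + count(node$left) + count(node$right)
  }
  count(tree$root)
}
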