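# Expression and covariate preprocessing: sex adjustment, IQR filtering,
# log2 transform, mean imputation, quantile allergy levels. Order of the
# expression chain is fixed: sex-adjust -> IQR filter -> log2.

#' Remove a global sex effect from expression values
#'
#' Blood gene expression in mixed-sex pediatric cohorts carries a global
#' sex effect that can dominate gene-covariate correlations. Per gene, a
#' linear model `value ~ intercept + sex` is fitted and the residuals are
#' kept. Because downstream steps log2-transform the matrix, the gene's
#' grand mean is added back to the residuals so values stay positive and
#' each gene keeps its location while losing the sex contrast (for a
#' binary covariate, least squares equals group-mean centering).
#'
#' @param expr an `expression_matrix` with `scale_tag = "intensity"`.
#' @param sex per-subject binary factor/character/logical vector, named by
#'   subject id or in subject order; exactly two levels must be present.
#' @return An `expression_matrix` with `scale_tag = "sex_adjusted"`.
#' @export
adjust_for_sex <- function(expr, sex) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!expr$scale_tag %in% c("intensity", "sex_adjusted"))
    stop("adjust_for_sex expects an intensity or sex_adjusted matrix, got ",
         expr$scale_tag)
  sex <- .match_subject_vector(sex, expr$subject_ids, "sex")
  if (anyNA(sex)) stop("sex must be known for every subject")
  f <- factor(sex)
  if (nlevels(f) != 2)
    stop("sex adjustment needs exactly two sexes present (got ",
         nlevels(f), ")")
  if (any(table(f) < 2)) stop("need >=2 subjects of each sex")
  grp <- split(seq_along(f), f)
  vals <- expr$values
  grand <- rowMeans(vals)
  out <- vals
  for (ix in grp) {
    gm <- rowMeans(vals[, ix, drop = FALSE])
    out[, ix] <- vals[, ix, drop = FALSE] - gm + grand
  }
  expression_matrix(out, scale_tag = "sex_adjusted")
}

.match_subject_vector <- function(x, subject_ids, what) {
  if (!is.null(names(x))) {
    miss <- setdiff(subject_ids, names(x))
    if (length(miss))
      stop(what, " missing for subject(s): ", paste(miss, collapse = ", "))
    x[subject_ids]
  } else {
    if (length(x) != length(subject_ids))
      stop(what, " must be named or match the number of subjects")
    x
  }
}

#' Filter genes by inter-quartile intensity range
#'
#' Keeps exactly the genes whose IQR (Q3 - Q1, linear-interpolation
#' "type 7" quantiles) is strictly greater than `threshold`. The default
#' threshold of 2000 intensity units assumes a MAS5-like scale and selects
#' genes with meaningful variation across subjects.
#'
#' @param expr an `expression_matrix`.
#' @param threshold non-negative IQR cutoff in the matrix's units.
#' @return list with `expr` (the filtered matrix), `kept_gene_ids`, and
#'   `iqr` (named per-gene IQR vector).
#' @export
iqr_filter <- function(expr, threshold = 2000) {
  stopifnot(inherits(expr, "expression_matrix"), threshold >= 0)
  qs <- matrixStats_rowQuantiles(expr$values, probs = c(0.25, 0.75))
  iqr <- qs[, 2] - qs[, 1]
  keep <- iqr > threshold
  if (!any(keep))
    message("iqr_filter: no genes exceed IQR threshold ", threshold)
  kept <- expr$gene_ids[keep]
  out <- if (any(keep))
    expression_matrix(expr$values[keep, , drop = FALSE],
                      scale_tag = expr$scale_tag)
  else NULL
  list(expr = out, kept_gene_ids = kept, iqr = setNames(iqr, expr$gene_ids))
}

# row-wise type-7 quantiles without extra dependencies
matrixStats_rowQuantiles <- function(m, probs) {
  t(apply(m, 1, stats::quantile, probs = probs, type = 7, names = FALSE))
}

#' Log2-transform a sex-adjusted expression matrix
#'
#' Values at or below `floor_value` are clamped to `floor_value` before
#' the elementwise log2 (sex-adjusted intensities are positive by
#' construction except in pathological cases; the clamp count is
#' reported via `message`).
#'
#' @param expr an `expression_matrix` with `scale_tag = "sex_adjusted"`.
#' @param floor_value positive floor applied before the transform.
#' @return An `expression_matrix` with `scale_tag = "log2"`.
#' @export
log2_transform <- function(expr, floor_value = 1.0) {
  stopifnot(inherits(expr, "expression_matrix"), floor_value > 0)
  if (expr$scale_tag != "sex_adjusted")
    stop("log2_transform expects a sex_adjusted matrix, got ", expr$scale_tag)
  v <- expr$values
  n_clamped <- sum(v <= floor_value)
  if (n_clamped > 0)
    message("log2_transform: clamped ", n_clamped, " value(s) to ",
            floor_value)
  v[v <= floor_value] <- floor_value
  expression_matrix(log2(v), scale_tag = "log2")
}

#' Mean-impute missing covariate values
#'
#' Each missing cell is replaced by its covariate's observed mean. The
#' per-covariate imputation counts are attached as attribute
#' `"imputation_counts"`.
#'
#' @param cov a `covariate_table`.
#' @return A complete `covariate_table`.
#' @export
mean_impute <- function(cov) {
  stopifnot(inherits(cov, "covariate_table"))
  v <- cov$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0))
    stop("covariate(s) fully missing: ",
         paste(cov$covariate_ids[n_obs == 0], collapse = ", "))
  counts <- colSums(is.na(v))
  if (any(counts > 0)) {
    mu <- colMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- mu[idx[, 2]]
  }
  out <- covariate_table(v, categories = cov$categories, units = cov$units)
  attr(out, "imputation_counts") <- setNames(counts, cov$covariate_ids)
  out
}

#' Ordinal allergy levels from a continuous allergen summary
#'
#' Bins a continuous allergen summary (e.g. an aeroallergen or food
#' allergen screen) into `n_levels` equal-probability quantile bins
#' (type-7 quantiles). Level 0 is "not allergic", level `n_levels - 1`
#' "highly allergic". A value equal to a cut point goes to the lower bin.
#' With fewer distinct cut points than bins the bins collapse with a
#' warning; `NA` input yields `NA` levels.
#'
#' @param values numeric vector of per-subject summaries.
#' @param n_levels number of ordinal levels (default 5).
#' @return integer vector of levels in `0:(n_levels-1)`.
#' @export
allergy_levels <- function(values, n_levels = 5) {
  stopifnot(n_levels >= 2)
  obs <- values[!is.na(values)]
  if (!length(obs)) stop("no observed values to bin")
  cuts <- stats::quantile(obs, probs = seq_len(n_levels - 1) / n_levels,
                          type = 7, names = FALSE)
  dup <- duplicated(cuts)
  if (length(unique(obs)) < n_levels || any(dup))
    warning("fewer distinct values than bins; some allergy levels collapse")
  # (a, b] intervals: ties at a cut point fall to the lower bin
  lev <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  lev[ok] <- vapply(values[ok], function(x) sum(x > cuts), integer(1))
  lev
}

#' Split a covariate table into continuous covariates and allergy summaries
#'
#' Removes the allergy-indicator covariates (categories `allergen_screen`
#' and `serum_allergen`) from the table, returning the remaining
#' continuous covariates plus the phadiatop and foodscreen summary vectors
#' for quantile categorization. Highly correlated, detection-limit-imputed
#' serum allergens would otherwise overweight mixed-domain clustering.
#'
#' @param cov a `covariate_table` with categories assigned.
#' @param phadiatop_id,foodscreen_id covariate ids of the two screening
#'   summaries; by default the first covariate whose id matches
#'   `"phadiatop"` / `"foodscreen"` (case-insensitive).
#' @return list with `continuous` (a `covariate_table`), `phadiatop`,
#'   `foodscreen` (named numeric vectors or `NULL` when absent), and
#'   `removed_ids`.
#' @export
split_covariates <- function(cov, phadiatop_id = NULL, foodscreen_id = NULL) {
  stopifnot(inherits(cov, "covariate_table"))
  allergy <- cov$covariate_ids[cov$categories[cov$covariate_ids] %in%
                                 .allergy_categories]
  keep <- setdiff(cov$covariate_ids, allergy)
  if (!length(keep)) stop("no continuous covariates remain after removal")
  find_id <- function(given, pattern) {
    if (!is.null(given)) return(given)
    hit <- grep(pattern, cov$covariate_ids, ignore.case = TRUE, value = TRUE)
    if (length(hit)) hit[1] else NULL
  }
  pid <- find_id(phadiatop_id, "phadiatop")
  fid <- find_id(foodscreen_id, "foodscreen")
  getvec <- function(id) if (is.null(id)) NULL else
    setNames(cov$values[, id], cov$subject_ids)
  continuous <- covariate_table(cov$values[, keep, drop = FALSE],
                                categories = cov$categories[keep],
                                units = cov$units[keep])
  list(continuous = continuous, phadiatop = getvec(pid),
       foodscreen = getvec(fid), removed_ids = allergy)
}
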