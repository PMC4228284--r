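# ---- controlled vocabularies --------------------------------------------

.scale_tags <- c("intensity", "sex_adjusted", "log2")

.covariate_categories <- c(
  "allergen_screen", "blood_chemistry", "CBC", "clinic", "hematology",
  "inflammatory", "lipids", "lung_function", "serum_allergen", "unspecified"
)

.allergy_categories <- c("allergen_screen", "serum_allergen")

.asthma_levels <- c("asthmatic", "non_asthmatic", "unknown")
.yesno_levels <- c("yes", "no", "unknown")
.allergy_level_tokens <- c("0", "1", "2", "3", "4", "unknown")

#' Construct an expression matrix
#'
#' A gene-by-subject matrix of expression values with named, unique axes and
#' a scale tag tracking its position in the preprocessing chain
#' (`intensity` -> `sex_adjusted` -> `log2`). Values must be complete and
#' finite: the pipeline assumes no missing expression data.
#'
#' @param values numeric matrix, genes in rows, subjects in columns.
#' @param gene_ids,subject_ids character vectors naming rows/columns; taken
#'   from `dimnames(values)` when omitted.
#' @param scale_tag one of `"intensity"`, `"sex_adjusted"`, `"log2"`.
#' @return An object of class `expression_matrix` with fields `values`,
#'   `gene_ids`, `subject_ids`, `scale_tag`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              subject_ids = colnames(values),
                              scale_tag = "intensity") {
  values <- as.matrix(values)
  scale_tag <- match.arg(scale_tag, .scale_tags)
  gene_ids <- as.character(gene_ids)
  subject_ids <- as.character(subject_ids)
  if (length(gene_ids) != nrow(values) || length(subject_ids) != ncol(values))
    stop("gene_ids/subject_ids must match the matrix dimensions")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                       collapse = ", "))
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be complete and finite")
  dimnames(values) <- list(gene_ids, subject_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 subject_ids = subject_ids, scale_tag = scale_tag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d subjects [%s scale]\n",
              length(x$gene_ids), length(x$subject_ids), x$scale_tag))
  invisible(x)
}

#' Construct a covariate table
#'
#' Subjects-by-covariates matrix of continuous clinical/demographic
#' covariates. Missing values are stored as `NA` (the explicit missing
#' mask is `is.na(values)`); imputation is a separate, auditable step.
#'
#' @param values numeric matrix, subjects in rows, covariates in columns;
#'   `NA` marks a missing measurement.
#' @param subject_ids,covariate_ids axis names (default: dimnames).
#' @param categories named character vector mapping covariate id to one of
#'   the covariate categories (allergen_screen, blood_chemistry, CBC,
#'   clinic, hematology, inflammatory, lipids, lung_function,
#'   serum_allergen, unspecified). Unlisted covariates get "unspecified".
#' @param units optional named character vector of unit strings.
#' @return An object of class `covariate_table`.
#' @export
covariate_table <- function(values, subject_ids = rownames(values),
                            covariate_ids = colnames(values),
                            categories = NULL, units = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  subject_ids <- as.character(subject_ids)
  covariate_ids <- as.character(covariate_ids)
  if (length(subject_ids) != nrow(values) ||
      length(covariate_ids) != ncol(values))
    stop("subject_ids/covariate_ids must match the matrix dimensions")
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (anyDuplicated(covariate_ids)) stop("duplicate covariate ids")
  dimnames(values) <- list(subject_ids, covariate_ids)
  cats <- setNames(rep("unspecified", length(covariate_ids)), covariate_ids)
  if (!is.null(categories)) {
    bad <- setdiff(categories, .covariate_categories)
    if (length(bad))
      stop("unknown covariate categories: ", paste(unique(bad), collapse = ", "),
           "; allowed: ", paste(.covariate_categories, collapse = ", "))
    cats[intersect(names(categories), covariate_ids)] <-
      categories[intersect(names(categories), covariate_ids)]
  }
  u <- setNames(rep("", length(covariate_ids)), covariate_ids)
  if (!is.null(units))
    u[intersect(names(units), covariate_ids)] <-
      units[intersect(names(units), covariate_ids)]
  structure(list(values = values, subject_ids = subject_ids,
                 covariate_ids = covariate_ids, categories = cats, units = u),
            class = "covariate_table")
}

#' Missing-value mask of a covariate table
#' @param cov a `covariate_table`.
#' @return logical matrix, `TRUE` where the measurement is missing.
#' @export
missing_mask <- function(cov) {
  stopifnot(inherits(cov, "covariate_table"))
  is.na(cov$values)
}

#' @export
print.covariate_table <- function(x, ...) {
  cat(sprintf("covariate_table: %d subjects x %d covariates (%d missing cells)\n",
              length(x$subject_ids), length(x$covariate_ids),
              sum(is.na(x$values))))
  invisible(x)
}

#' Construct a disease-indicator set
#'
#' Per-subject categorical indicators of asthma/allergy status.
#' `confirmed_asthma` is the supervision label for the decision tree;
#' subjects with value `"unknown"` are excluded from tree fitting and
#' accuracy computations.
#'
#' @param subject_ids character vector.
#' @param confirmed_asthma values in `asthmatic`/`non_asthmatic`/`unknown`.
#' @param current_asthma,questionnaire_asthma values in `yes`/`no`/`unknown`.
#' @param phadiatop_level,foodscreen_level ordinal allergy levels `0`..`4`
#'   (`0` = not allergic, `4` = highly allergic) or `unknown`.
#' @return An object of class `indicator_set` wrapping a data.frame.
#' @export
indicator_set <- function(subject_ids, confirmed_asthma,
                          current_asthma = "unknown",
                          questionnaire_asthma = "unknown",
                          phadiatop_level = "unknown",
                          foodscreen_level = "unknown") {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  n <- length(subject_ids)
  chk <- function(x, allowed, what) {
    x <- as.character(rep_len(x, n))
    bad <- setdiff(x, allowed)
    if (length(bad))
      stop(sprintf("invalid %s value(s) %s; allowed: %s", what,
                   paste(sQuote(unique(bad)), collapse = ", "),
                   paste(allowed, collapse = ", ")))
    x
  }
  df <- data.frame(
    subject_id = subject_ids,
    confirmed_asthma = chk(confirmed_asthma, .asthma_levels, "confirmed_asthma"),
    current_asthma = chk(current_asthma, .yesno_levels, "current_asthma"),
    questionnaire_asthma = chk(questionnaire_asthma, .yesno_levels,
                               "questionnaire_asthma"),
    phadiatop_level = chk(phadiatop_level, .allergy_level_tokens,
                          "phadiatop_level"),
    foodscreen_level = chk(foodscreen_level, .allergy_level_tokens,
                           "foodscreen_level"),
    stringsAsFactors = FALSE
  )
  structure(list(data = df, subject_ids = subject_ids),
            class = "indicator_set")
}

#' @export
print.indicator_set <- function(x, ...) {
  tab <- table(x$data$confirmed_asthma)
  cat(sprintf("indicator_set: %d subjects (confirmed_asthma: %s)\n",
              nrow(x$data),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Supervision labels from an indicator set
#'
#' Returns the binary confirmed-asthma label for subjects with known
#' status, dropping `"unknown"` subjects.
#'
#' @param ind an `indicator_set`.
#' @return named character vector with values `asthmatic`/`non_asthmatic`.
#' @export
asthma_labels <- function(ind) {
  stopifnot(inherits(ind, "indicator_set"))
  keep <- ind$data$confirmed_asthma != "unknown"
  setNames(ind$data$confirmed_asthma[keep], ind$data$subject_id[keep])
}

# ---- pipeline configuration ---------------------------------------------

#' Pipeline configuration
#'
#' Collects the tunable parameters of the multi-step decision-tree method.
#' Defaults follow the published analysis of the 146-subject asthma cohort:
#' family alpha 0.05 Bonferroni-divided across the covariate tests
#' (0.05/81 ~ 0.0006), IQR filter at 2000 intensity units, metagene
#' variance threshold 5%, 11 gene clusters, minimum terminal-leaf size 14
#' (= floor of 10% of 146 labeled subjects), 10,000 bootstrap resamples.
#'
#' @param family_alpha family-wise alpha for the covariate screen.
#' @param n_covariate_tests Bonferroni divisor; `NULL` means "use the number
#'   of covariates at run time".
#' @param iqr_threshold intensity-scale inter-quartile-range cutoff (scale
#'   dependent; 2000 assumes a MAS5-like median-500 intensity scale).
#' @param variance_fraction_min minimum per-component variance fraction for
#'   a principal component to become a metagene.
#' @param n_gene_clusters number of gene clusters cut from the dendrogram.
#' @param min_leaf_fraction minimum leaf size as a fraction of labeled
#'   subjects, used when `min_leaf_override` is `NULL`.
#' @param min_leaf_override explicit minimum leaf size (default 14).
#' @param bootstrap_reps bootstrap resamples for tree evaluation.
#' @param rng_seed integer seed recorded with the run.
#' @param gene_ttest_alpha per-gene alpha for the t-test baseline.
#' @param gain_epsilon minimum information gain (bits) for a split.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(family_alpha = 0.05, n_covariate_tests = NULL,
                            iqr_threshold = 2000,
                            variance_fraction_min = 0.05,
                            n_gene_clusters = 11, min_leaf_fraction = 0.10,
                            min_leaf_override = 14, bootstrap_reps = 10000,
                            rng_seed = 1L, gene_ttest_alpha = 0.05,
                            gain_epsilon = 1e-6) {
  stopifnot(family_alpha > 0, family_alpha < 1,
            iqr_threshold >= 0,
            variance_fraction_min > 0, variance_fraction_min < 1,
            min_leaf_fraction > 0, min_leaf_fraction < 1,
            n_gene_clusters >= 1, bootstrap_reps >= 1,
            gene_ttest_alpha > 0, gene_ttest_alpha < 1,
            gain_epsilon >= 0)
  if (!is.null(n_covariate_tests)) stopifnot(n_covariate_tests >= 1)
  if (!is.null(min_leaf_override)) stopifnot(min_leaf_override >= 2)
  structure(list(family_alpha = family_alpha,
                 n_covariate_tests = n_covariate_tests,
                 iqr_threshold = iqr_threshold,
                 variance_fraction_min = variance_fraction_min,
                 n_gene_clusters = as.integer(n_gene_clusters),
                 min_leaf_fraction = min_leaf_fraction,
                 min_leaf_override = min_leaf_override,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 rng_seed = as.integer(rng_seed),
                 gene_ttest_alpha = gene_ttest_alpha,
                 gain_epsilon = gain_epsilon),
            class = "pipeline_config")
}

#' Effective minimum leaf size
#'
#' `min_leaf_override` when set, otherwise
#' `floor(min_leaf_fraction * n_labeled_subjects)`, never below 2.
#'
#' @param config a `pipeline_config`.
#' @param n_labeled number of subjects with known supervision label.
#' @return integer minimum leaf size.
#' @export
effective_min_leaf <- function(config, n_labeled) {
  stopifnot(inherits(config, "pipeline_config"), n_labeled >= 0)
  ml <- if (!is.null(config$min_leaf_override)) config$min_leaf_override
        else floor(config$min_leaf_fraction * n_labeled)
  max(2L, as.integer(ml))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors [pipeline_config()] field names; absent fields
#' keep their defaults, unknown fields are an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

# ---- readers / writers ---------------------------------------------------

#' Read a gene-expression TSV
#'
#' Tab-delimited text, genes in rows and subjects in columns: header row of
#' subject ids with leading column `gene_id`. The body must be complete
#' numeric (the method assumes no missing expression values).
#'
#' @param path file path.
#' @param scale_tag scale of the stored values (default `"intensity"`).
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, scale_tag = "intensity") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene_id")
    stop("expression TSV must have first column 'gene_id' and >=1 subject")
  gene_ids <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric or missing expression cell at gene '%s', subject '%s' (value '%s'); expression must be complete",
      gene_ids[idx[1]], colnames(body)[idx[2]], body[idx[1], idx[2]]))
  }
  dimnames(num) <- list(gene_ids, colnames(body))
  expression_matrix(num, scale_tag = scale_tag)
}

#' Write a gene-expression TSV
#' @param expr an `expression_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = expr$gene_ids,
                   format(expr$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  names(df) <- c("gene_id", expr$subject_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a covariate CSV
#'
#' CSV with header, first column `subject_id`; empty cells or `NA` mark
#' missing measurements. An optional dictionary CSV
#' (`covariate_id,category,unit`) attaches categories and units.
#'
#' @param path covariate CSV path.
#' @param dictionary_path optional covariate dictionary CSV path.
#' @return A `covariate_table`.
#' @export
read_covariates <- function(path, dictionary_path = NULL) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "subject_id")
    stop("covariate CSV must have first column 'subject_id'")
  subj <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  body[body == ""] <- NA
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- is.na(num) & !is.na(body) & body != "NA"
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric covariate cell at subject '%s', covariate '%s'",
                 subj[idx[1]], colnames(body)[idx[2]]))
  }
  dimnames(num) <- list(subj, colnames(body))
  categories <- units <- NULL
  if (!is.null(dictionary_path)) {
    dict <- utils::read.csv(dictionary_path, header = TRUE,
                            colClasses = "character")
    need <- c("covariate_id", "category")
    if (!all(need %in% names(dict)))
      stop("covariate dictionary needs columns covariate_id, category")
    categories <- setNames(dict$category, dict$covariate_id)
    if ("unit" %in% names(dict)) units <- setNames(dict$unit, dict$covariate_id)
  }
  covariate_table(num, categories = categories, units = units)
}

#' Write a covariate CSV (and optional dictionary)
#' @param cov a `covariate_table`.
#' @param path output CSV path.
#' @param dictionary_path optional path for the covariate dictionary CSV.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path, dictionary_path = NULL) {
  stopifnot(inherits(cov, "covariate_table"))
  body <- matrix("", nrow(cov$values), ncol(cov$values))
  obs <- !is.na(cov$values)
  body[obs] <- format(cov$values[obs], digits = 17, trim = TRUE,
                      scientific = FALSE)
  df <- data.frame(subject_id = cov$subject_ids, body, check.names = FALSE)
  names(df) <- c("subject_id", cov$covariate_ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(dictionary_path))
    utils::write.csv(data.frame(covariate_id = cov$covariate_ids,
                                category = unname(cov$categories),
                                unit = unname(cov$units)),
                     dictionary_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a disease-indicator CSV
#'
#' CSV with header, first column `subject_id`, remaining columns among
#' `confirmed_asthma`, `current_asthma`, `questionnaire_asthma`,
#' `phadiatop_level`, `foodscreen_level` using the controlled vocabularies
#' of [indicator_set()]; unknown tokens are rejected.
#'
#' @param path indicator CSV path.
#' @return An `indicator_set`.
#' @export
read_indicators <- function(path) {
  if (!file.exists(path)) stop("indicator file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "subject_id")
    stop("indicator CSV must have first column 'subject_id'")
  get <- function(col) if (col %in% names(df)) df[[col]] else "unknown"
  indicator_set(df$subject_id,
                confirmed_asthma = get("confirmed_asthma"),
                current_asthma = get("current_asthma"),
                questionnaire_asthma = get("questionnaire_asthma"),
                phadiatop_level = get("phadiatop_level"),
                foodscreen_level = get("foodscreen_level"))
}

#' Write a disease-indicator CSV
#' @param ind an `indicator_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(ind, path) {
  stopifnot(inherits(ind, "indicator_set"))
  utils::write.csv(ind$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align expression, covariate, and indicator tables on shared subjects
#'
#' Joins the three tables on `subject_id`, keeping exactly the
#' intersection. Subjects present in one table but not another are dropped
#' with a warning naming the count, mirroring cohort assembly where
#' subjects with incomplete records are excluded at join time.
#'
#' @param expr an `expression_matrix`.
#' @param cov a `covariate_table`.
#' @param ind an `indicator_set`.
#' @return list with aligned `expression`, `covariates`, `indicators`,
#'   `subject_ids`, and `n_dropped`.
#' @export
align_cohort <- function(expr, cov, ind) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(cov, "covariate_table"),
            inherits(ind, "indicator_set"))
  shared <- Reduce(intersect, list(expr$subject_ids, cov$subject_ids,
                                   ind$subject_ids))
  if (length(shared) == 0) stop("no shared subjects across the three tables")
  total <- length(unique(c(expr$subject_ids, cov$subject_ids,
                           ind$subject_ids)))
  n_dropped <- total - length(shared)
  if (n_dropped > 0)
    warning(sprintf("dropping %d subject(s) absent from at least one table",
                    n_dropped))
  shared <- expr$subject_ids[expr$subject_ids %in% shared]  # keep expr order
  idx <- match(shared, ind$subject_ids)
  ind2 <- indicator_set(shared,
                        ind$data$confirmed_asthma[idx],
                        ind$data$current_asthma[idx],
                        ind$data$questionnaire_asthma[idx],
                        ind$data$phadiatop_level[idx],
                        ind$data$foodscreen_level[idx])
  list(expression = expression_matrix(expr$values[, shared, drop = FALSE],
                                      scale_tag = expr$scale_tag),
       covariates = covariate_table(cov$values[shared, , drop = FALSE],
                                    categories = cov$categories,
                                    units = cov$units),
       indicators = ind2,
       subject_ids = shared,
       n_dropped = n_dropped)
}
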