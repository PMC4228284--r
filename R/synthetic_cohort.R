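# Synthetic cohorts with the causal structure the pipeline exploits:
# planted endotypes shift a disjoint set of "active" clinical covariates,
# sparse gene loadings propagate covariates into log2 expression (plus a
# global linear sex effect and Gaussian noise), exponentiation puts the
# matrix on an intensity scale, and disease indicators are noisy copies of
# the endotype class. A block of highly correlated allergen covariates
# with constant detection-limit imputation emulates the serum-allergen
# panel that motivates collapsing them before mixed-domain clustering.

#' Synthetic cohort configuration
#'
#' Defaults emulate a pediatric asthma cohort: 205 enrolled subjects of
#' whom 146 have a known confirmed-asthma status, 81 covariates of which
#' 14 form the allergy-indicator block, ~2% missing covariate cells, four
#' planted endotypes (two asthmatic, two non-asthmatic), a standardized
#' covariate shift of 1.5 per endotype-active covariate, and 5% label
#' noise reflecting conflicting asthma-status definitions.
#'
#' Unstated-by-design constants chosen once (see the methods vignette):
#' expression noise sd 0.4 and sex-effect sd 0.3 on the log2 scale;
#' linked genes draw baselines in log2 [12.3, 13.5] and background genes
#' in [8, 11.7], so linked genes clear the default IQR-2000 intensity
#' filter while background genes do not; gene-covariate loading magnitudes
#' are uniform in [0.25, 0.5] with random sign (keeping intensity-scale
#' sex residuals positive); each endotype activates 8
#' covariates; allergen-block pairwise correlation ~0.8.
#'
#' @param n_subjects,n_known_status cohort size and labeled subset size.
#' @param n_genes,n_covariates,n_allergy_covariates dimensions; the
#'   allergy block is 3 screen summaries (phadiatop, foodscreen,
#'   total IgE) plus `n_allergy_covariates - 3` serum allergens.
#' @param n_endotypes number of planted endotypes (alternating classes,
#'   at least one per class).
#' @param covariate_effect_size standardized mean shift of an
#'   endotype-active covariate.
#' @param gene_loading_density probability that a given gene loads on a
#'   given non-allergy covariate.
#' @param expression_noise_sd,sex_effect_sd log2-scale noise levels.
#' @param covariate_missing_rate fraction of covariate cells masked.
#' @param detection_limit_quantile allergen values below this quantile
#'   are replaced by the constant detection-limit value.
#' @param label_noise_rate probability the confirmed-asthma label flips.
#' @param n_active_covariates endotype-active covariates per endotype.
#' @param rng_seed integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 205, n_known_status = 146,
                             n_genes = 1500, n_covariates = 81,
                             n_allergy_covariates = 14, n_endotypes = 4,
                             covariate_effect_size = 1.5,
                             gene_loading_density = 0.05,
                             expression_noise_sd = 0.4,
                             sex_effect_sd = 0.3,
                             covariate_missing_rate = 0.02,
                             detection_limit_quantile = 0.6,
                             label_noise_rate = 0.05,
                             n_active_covariates = 8,
                             rng_seed = 1L) {
  stopifnot(n_known_status <= n_subjects, n_endotypes >= 2,
            n_allergy_covariates >= 3,
            n_allergy_covariates < n_covariates,
            covariate_missing_rate >= 0, covariate_missing_rate <= 1,
            detection_limit_quantile >= 0, detection_limit_quantile <= 1,
            label_noise_rate >= 0, label_noise_rate <= 1,
            gene_loading_density >= 0, gene_loading_density <= 1,
            covariate_effect_size >= 0, n_active_covariates >= 1)
  if (n_endotypes * n_active_covariates >
      n_covariates - n_allergy_covariates)
    stop("not enough non-allergy covariates for disjoint active sets")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a cohort with planted endotypes
#'
#' See [synthetic_config()] for the generative model. The returned truth
#' object is emitted alongside the data and is never consumed by the
#' pipeline.
#'
#' @param config a `synthetic_config`.
#' @param seed optional seed overriding `config$rng_seed`.
#' @return list with `expression` (`expression_matrix`, intensity scale),
#'   `covariates` (`covariate_table` with missing cells), `indicators`
#'   (`indicator_set`), and `truth` (endotype/class/sex per subject,
#'   active covariate sets, loading matrix).
#' @export
simulate_cohort <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) seed <- config$rng_seed
  withr_seed(seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  subj <- sprintf("S%03d", seq_len(n))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))

  # endotypes alternate classes: odd endotypes asthmatic, even non-asthmatic
  endotype <- sample(rep_len(seq_len(cfg$n_endotypes), n))
  endo_class <- ifelse(seq_len(cfg$n_endotypes) %% 2 == 1,
                       "asthmatic", "non_asthmatic")
  class_true <- endo_class[endotype]
  sex <- sample(c("F", "M"), n, replace = TRUE)

  # covariate roster: allergy block first, then continuous clinical ones
  n_serum <- cfg$n_allergy_covariates - 3
  allergy_ids <- c("phadiatop", "foodscreen", "total_ige",
                   sprintf("serum_allergen_%02d", seq_len(n_serum)))
  n_cont <- cfg$n_covariates - cfg$n_allergy_covariates
  cont_ids <- sprintf("cov_%03d", seq_len(n_cont))
  cont_cats <- rep_len(c("blood_chemistry", "CBC", "clinic", "hematology",
                         "inflammatory", "lipids", "lung_function"), n_cont)
  categories <- setNames(c("allergen_screen", "allergen_screen",
                           "allergen_screen", rep("serum_allergen", n_serum),
                           cont_cats),
                         c(allergy_ids, cont_ids))

  # endotype-active covariates: disjoint draws from the continuous pool
  pool <- sample(cont_ids)
  active <- split(pool[seq_len(cfg$n_endotypes * cfg$n_active_covariates)],
                  rep(seq_len(cfg$n_endotypes),
                      each = cfg$n_active_covariates))
  names(active) <- paste0("endotype_", seq_len(cfg$n_endotypes))

  # continuous covariates: standard normal + effect-size shift when active
  Ccont <- matrix(stats::rnorm(n * n_cont), n, n_cont,
                  dimnames = list(subj, cont_ids))
  for (e in seq_len(cfg$n_endotypes)) {
    ix <- endotype == e
    Ccont[ix, active[[e]]] <- Ccont[ix, active[[e]]] +
      cfg$covariate_effect_size
  }

  # allergen block: correlated (r ~ 0.8) noisy copies of a latent allergy
  # score that is mildly elevated in asthmatic endotypes
  latent_allergy <- 0.8 * (class_true == "asthmatic") + stats::rnorm(n)
  r_block <- 0.8
  Call <- sapply(seq_along(allergy_ids), function(j)
    sqrt(r_block) * latent_allergy + sqrt(1 - r_block) * stats::rnorm(n))
  dimnames(Call) <- list(subj, allergy_ids)

  # expression: sparse loadings over the continuous covariates
  L <- matrix(0, cfg$n_genes, n_cont, dimnames = list(genes, cont_ids))
  nz <- matrix(stats::runif(length(L)) < cfg$gene_loading_density,
               nrow(L), ncol(L))
  L[nz] <- stats::runif(sum(nz), 0.25, 0.5) *
    sample(c(-1, 1), sum(nz), replace = TRUE)
  linked <- rowSums(nz) > 0
  baseline <- ifelse(linked, stats::runif(cfg$n_genes, 12.3, 13.5),
                     stats::runif(cfg$n_genes, 8, 11.7))
  beta_sex <- stats::rnorm(cfg$n_genes, 0, cfg$sex_effect_sd)
  log2expr <- baseline + L %*% t(Ccont) +
    outer(beta_sex, as.numeric(sex == "F")) +
    matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$expression_noise_sd),
           cfg$n_genes, n)
  expr <- expression_matrix(2^log2expr, gene_ids = genes,
                            subject_ids = subj, scale_tag = "intensity")

  # serum allergens: constant imputation below the detection limit
  Cobs <- cbind(Call, Ccont)
  serum_ids <- allergy_ids[-(1:3)]
  for (id in serum_ids) {
    dl <- stats::quantile(Cobs[, id], cfg$detection_limit_quantile,
                          type = 7, names = FALSE)
    Cobs[Cobs[, id] < dl, id] <- dl
  }

  # missingness mask (covariates only; expression stays complete)
  mask <- matrix(stats::runif(length(Cobs)) < cfg$covariate_missing_rate,
                 nrow(Cobs), ncol(Cobs))
  Cobs[mask] <- NA
  covariates <- covariate_table(Cobs, categories = categories)

  # indicators
  flip <- function(lab, rate, yes = "asthmatic", no = "non_asthmatic") {
    flips <- stats::runif(length(lab)) < rate
    ifelse(flips, ifelse(lab == yes, no, yes), lab)
  }
  confirmed <- flip(class_true, cfg$label_noise_rate)
  unknown_ix <- sample.int(n, n - cfg$n_known_status)
  confirmed[unknown_ix] <- "unknown"
  noisy_yes_no <- function(rate) {
    v <- flip(class_true, rate)
    ifelse(v == "asthmatic", "yes", "no")
  }
  current <- noisy_yes_no(2 * cfg$label_noise_rate)
  questionnaire <- noisy_yes_no(2 * cfg$label_noise_rate)
  phadiatop_level <- as.character(allergy_levels(Call[, "phadiatop"], 5))
  foodscreen_level <- as.character(allergy_levels(Call[, "foodscreen"], 5))
  indicators <- indicator_set(subj, confirmed, current, questionnaire,
                              phadiatop_level, foodscreen_level)

  truth <- structure(list(endotype = setNames(endotype, subj),
                          class = setNames(class_true, subj),
                          sex = setNames(sex, subj),
                          active_covariates = active,
                          loadings = L,
                          linked_genes = genes[linked],
                          latent_allergy = setNames(latent_allergy, subj)),
                     class = "synthetic_truth")
  list(expression = expr, covariates = covariates, indicators = indicators,
       truth = truth)
}

#' Chance-corrected recovery of planted endotypes
#'
#' Adjusted Rand index between a discovered grouping (tree leaves or
#' clusters) and the planted endotypes: 1 = exact recovery, ~0 = chance.
#'
#' @param assignment named group ids per subject (e.g. leaf ids).
#' @param truth a `synthetic_truth` (or a named endotype vector).
#' @return adjusted Rand index in `[-1, 1]`.
#' @export
truth_recovery_score <- function(assignment, truth) {
  tr <- if (inherits(truth, "synthetic_truth")) truth$endotype else truth
  if (is.null(names(assignment)) || is.null(names(tr)))
    stop("assignment and truth must be named by subject id")
  shared <- intersect(names(assignment), names(tr))
  if (!length(shared)) stop("no shared subjects to score")
  adjusted_rand_index(assignment[shared], tr[shared])
}

#' Adjusted Rand index between two partitions
#' @param a,b equal-length partition label vectors.
#' @return ARI; 1 for identical partitions, ~0 for random agreement.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Write a simulated cohort to disk
#' @param sim output of [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_covariates(sim$covariates, file.path(dir, "covariates.csv"),
                   file.path(dir, "covariate_dictionary.csv"))
  write_indicators(sim$indicators, file.path(dir, "indicators.csv"))
  utils::write.csv(data.frame(subject_id = names(sim$truth$sex),
                              sex = unname(sim$truth$sex)),
                   file.path(dir, "sex.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(endotype = as.list(truth$endotype),
         class = as.list(truth$class),
         sex = as.list(truth$sex),
         active_covariates = truth$active_covariates,
         linked_genes = truth$linked_genes),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
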