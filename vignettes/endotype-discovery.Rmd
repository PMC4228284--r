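---
title: "Endotype discovery with metagene decision trees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endotype discovery with metagene decision trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotree)
```

## The problem

Complex diseases such as childhood asthma are syndromes: several
mechanistically distinct subtypes (*endotypes*) produce overlapping
clinical pictures. When the goal is discovery of novel mechanisms rather
than refinement of known diagnostic criteria, the analysis must let the
data drive the grouping of subjects while still anchoring it to the
phenotype. `endotree` implements a multi-step procedure for cohorts with
three data domains: a gene-expression matrix (genes x subjects, an
MAS5-like positive intensity scale), a table of continuous
clinical/demographic covariates (subjects x covariates, possibly with
missing cells), and categorical disease-status indicators (confirmed,
current, and questionnaire-defined asthma, plus two ordinal allergy
screens).

## The multi-step decision-tree method

The pipeline has four analysis steps preceded by preprocessing.

**Preprocessing.** A global sex effect on blood gene expression is
removed by a per-gene linear adjustment: expression is regressed on sex
and the residuals are kept, *plus the gene's grand mean*. For a binary
covariate, least squares is exactly group-mean centering, so the
operation subtracts each sex's mean and restores the gene's location.
Adding the grand mean back is our resolution of an ambiguity in the
source procedure: raw residuals are signed, and the subsequent log2
transform needs positive values. Genes are then filtered by
inter-quartile range (IQR) of the sex-adjusted intensities — only genes
with IQR strictly greater than a threshold (default 2000 intensity
units, appropriate for a median-500-scaled chip; the threshold is scale
dependent and exposed) are kept — and finally log2 transformed, with
values at or below a floor (default 1.0) clamped and counted.

**Step 1 — covariate screening.** Every covariate is Pearson-correlated
with every remaining gene over pairwise-complete subjects (missing
covariate cells are dropped per pair; imputation is reserved for the
clustering baselines that require complete data). Two-sided p-values use
the exact t transform, t = r * sqrt(n-2) / sqrt(1-r^2) with n-2 degrees
of freedom. A gene is selected when its minimum p across covariates
falls below the Bonferroni per-test threshold alpha/m (0.05/81 ~ 0.0006
for the reference configuration). We implement the p-value rule, not the
"|r| > 0.23" shortcut sometimes quoted for this threshold: at n = 146
the exact transform puts the critical |r| near 0.28, so the shortcut is
not consistent with the stated alpha and is not used.

**Step 2 — gene clustering.** Selected genes are represented by their
profiles of absolute correlations |r| across covariates and agglomerated
by complete-linkage hierarchical clustering; the tree is cut at a
configured k (default 11). The profile distance is Euclidean — the
minimal reading of "clustering on the absolute correlation values" —
with Manhattan and correlation distances available as options. The
number of clusters has no published selection rule; the package reports
mean silhouette across k in [2, 20] as guidance
(`gene_cluster_k_guidance()`) but never auto-selects.

**Step 3 — metagenes.** Each gene cluster's expression block is centered
per gene (no unit-variance scaling: log2 expression is already on a
common scale; scaling is available as a sensitivity flag) and decomposed
by SVD. Every principal component explaining at least 5% of the
cluster's variance becomes a *metagene*: a subject-wise score vector,
named `<cluster>-<component>` (e.g. `F-2`). Retaining lower components
captures aspects of cluster variation beyond the dominant one; the
"fuzzy sub-clustering" effect — a gene contributing to several
components — is inherent to PCA. PCA sign is fixed by making each
loading vector's largest-magnitude element positive, so runs are
reproducible.

**Step 4 — the tree.** A decision tree over metagene scores is grown to
segregate subjects by confirmed asthma status. At each node the
(metagene, threshold) pair with maximal information gain (reduction of
Shannon entropy of the label, in bits) is chosen among splits leaving at
least `min_leaf` subjects per side; candidate thresholds are midpoints
between consecutive distinct scores. We use plain information gain, not
the gain-ratio variant of C4.5: the method is described in terms of
information gain, and we implement the description rather than a
particular legacy tool's internals. Growth stops when a node is pure,
too small, or the best admissible gain does not exceed `gain_epsilon`
(default 1e-6 bits), which operationalizes "splits no longer improve
information gain". There is no post-pruning; the leaf-size constraint
(default 14, i.e. floor(10% x 146)) is the only regularizer. Ties among
equal-gain splits go to the smaller threshold, then the
lexicographically first metagene — determinism over fidelity to any
particular implementation.

**Evaluation.** Leaves are labeled by training majority (ties to
non-asthmatic, the conservative call). We report overall segregation
accuracy (sum of leaf majority counts / n, as a percent), counts of
asthmatic/non-asthmatic leaves, per-leaf percent correct, and a
bootstrap: B resamples of subjects with replacement (default 10,000) are
routed through the *fixed* tree and scored against the resampled labels.
The summarized statistic is the mean with a 2.5/97.5 percentile
interval; the source material calls this "an estimate of predictive
ability" without naming the statistic, so the mean-accuracy reading is
flagged as an interpretation. Resubstitution-style bootstrap of a fixed
classifier estimates stability, not out-of-sample error.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `family_alpha` | 0.05 | probability | conventional family-wise level for the covariate screen |
| `n_covariate_tests` | n covariates | count | Bonferroni divisor (81 in the reference cohort) |
| `iqr_threshold` | 2000 | intensity | variability filter; scale-dependent, assumes median-500 scaling |
| `variance_fraction_min` | 0.05 | proportion | minimum variance share for a metagene |
| `n_gene_clusters` | 11 | count | dendrogram cut; report-guided, never auto-selected |
| `min_leaf_fraction` / `min_leaf_override` | 0.10 / 14 | proportion / subjects | floor(10% of labeled subjects); 14 for n = 146 |
| `gain_epsilon` | 1e-6 | bits | "no further improvement" stop rule |
| `bootstrap_reps` | 10000 | count | evaluation resamples |

## Baselines

Three comparison methods frame the main pipeline:

* **Gene-wise two-sample t-tests** (pooled variance, two-sided; Welch by
  flag) with uncorrected and Bonferroni flags. On null data Bonferroni
  flags ~nothing, and uncorrected gene lists from two different label
  definitions overlap little — both behaviors are asserted in tests.
* **Single-domain clustering scored by internal validity indices.**
  `validity_scan()` clusters one domain over a grid of distance
  (Euclidean, Manhattan, Chebyshev, Canberra, Bray-Curtis, squared
  Euclidean) x method (k-means, PAM, single/complete/average/Ward
  linkage) x k, scoring mean silhouette (max is best), the Baker-Hubert
  Gamma rank statistic (max), and the Hubert-Levine C index (min).
  Infeasible combinations (k-means or Ward with non-Euclidean distances)
  are skipped and logged. The "generalized distance measure 1",
  McQuitty/median/centroid linkage, and DIANA present in the original
  software sweep are out of scope; the grid is extensible.
* **Modk-prototypes**, a k-means/k-modes hybrid over three weighted
  domains. The per-subject cost to a prototype is
  `w_e d2(expression) + w_c d2(clinical) + w_i d_match(indicators)` with
  squared Euclidean distances for the numeric blocks and simple matching
  (count of disagreeing attributes) for the categorical block. Numeric
  blocks are z-scored per variable before clustering so the domains are
  commensurate — the source standardizes prototypes for interpretation
  and is silent on pre-standardization; we standardize both. The exact
  adaptive-weight update of the original algorithm is not published in
  the text we implement from; our documented stand-in is
  `w_d proportional to 1/(1 + within-cluster cost_d)`, renormalized each
  iteration, so more compact domains gain weight. Prototype biomarkers:
  after standardizing prototypes to z-scores against each variable's
  overall mean/sd, clinical covariates are flagged at |z| > 1 and genes
  at |z| > 1.96 (the named alpha = 0.05 operationalized as the two-sided
  normal quantile, since no test is specified). Note an intrinsic
  ceiling: a cluster containing a fraction p of subjects cannot have a
  prototype z beyond sqrt((1-p)/p), so balanced two-cluster structures
  never reach the 1.96 gene threshold.
  Cluster accuracy uses all-subject majority accuracy, consistent with
  "segregation accuracy" (whether the original counted only asthmatics
  is ambiguous; our reading is recorded here).

## The synthetic cohort: what it emulates, and what a green test means

No clinical covariate data are published for the reference cohort, so
all quantitative validation runs on `simulate_cohort()`. The generator
is a linear-Gaussian structural model on the log2 scale, exponentiated
to intensities — the simplest structure satisfying every assumption the
pipeline exploits (linear sex effect, Pearson-detectable gene-covariate
links, covariate-separable endotypes):

1. each subject receives an endotype (default 4: two asthmatic, two
   non-asthmatic, balanced) and a sex;
2. each endotype "activates" 8 disjoint continuous covariates, shifting
   them by 1.5 sd for its subjects; the other covariates are standard
   normal;
3. a 14-covariate allergen block is drawn as r ~ 0.8 noisy copies of a
   latent allergy score (mildly elevated in asthmatics), and the 11
   serum-allergen columns are floored at their 0.6 quantile with a
   constant value — reproducing the detection-limit imputation artifact
   that motivates collapsing these covariates before mixed-domain
   clustering;
4. expression is `2^(baseline + loadings x covariates + sex effect + noise)`
   with sparse loadings (each gene-covariate pair links with
   probability 0.05, magnitudes uniform in [0.25, 0.5], random sign),
   noise sd 0.4 and sex-effect sd 0.3 on the log2 scale; linked genes
   draw baselines in log2 [12.3, 13.5] and background genes in
   [8, 11.7], so linked genes clear IQR 2000 and background genes
   essentially never do;
5. confirmed asthma is the endotype class flipped with probability 0.05
   (label noise mirroring conflicting status definitions), unknown for
   the unlabeled remainder (59 of 205 by default); the other indicators
   are noisier copies, and the allergy levels are quantile bins of the
   latent score;
6. 2% of covariate cells are masked missing.

The magnitudes in (4) were chosen once, for two reasons a cohort
scientist would recognize: per-gene signal of roughly one log2 unit is a
realistic effect size for blood expression, and — less obviously — the
intensity-scale sex adjustment subtracts group means from *raw*
intensities, so a heavy-tailed gene whose small values sit far below its
mean would be driven negative and clamped by the log2 floor. Loadings
much above 0.5 per covariate produce exactly that pathology.

A green endotype-recovery test therefore establishes: *when* covariates
separate endotypes, expression tracks covariates linearly, and labels
are mostly correct, the full chain (screen, cluster, metagenes, tree)
finds leaves aligned with the planted endotypes (>= 4 leaves at >= 90%
purity at n = 300). It does **not** establish robustness to probe-level
artifacts, batch effects, non-linear covariate-expression links,
cell-type composition shifts, or covariate sets biased toward one
disease process — all explicitly outside the generative model.

## Numerical choices and degenerate inputs

* Quantiles everywhere (IQR filter, allergy levels, detection limits)
  use linear interpolation between order statistics (R type 7), the most
  common convention; the source is silent.
* Allergy-level binning sends a value equal to a cut point to the lower
  bin; fewer distinct values than bins collapses bins with a warning.
* Zero-variance covariates or genes in the correlation screen yield
  r = 0, p = 1 with a warning, not an error.
* A single-gene cluster yields one metagene equal to the centered gene.
  A cluster whose *top* component falls below the variance threshold
  contributes no metagene (retaining it would break the variance-floor
  invariant); with no metagenes at all the pipeline returns a root-only
  majority tree rather than failing.
* Modk empty clusters are re-seeded with the subject farthest from its
  prototype; the objective is asserted non-increasing at fixed weights
  on every run.
* Bootstrap and Modk use an isolated RNG stream restored afterwards, so
  library calls do not perturb user seeds.

Two behaviors of plain information gain are worth knowing when reading
tree output. First, exactly balanced XOR structure has zero boundary
gain at the root — the greedy tree only resolves such interactions when
group sizes or class ratios break the symmetry. Second, with a small
`gain_epsilon` the tree keeps splitting into noise until the leaf-size
constraint binds; under label noise this yields extra small leaves that
isolate mislabeled subjects. Both are properties of the published
procedure, not artifacts of this implementation.

## Known limitations

* Probe-level processing (CEL parsing, MAS5/REDI normalization, globin
  reduction) is upstream and out of scope; the package consumes an
  already-normalized matrix.
* The IQR threshold is meaningful only on the intensity scale the data
  arrive on.
* Bonferroni across covariates is the implemented control; FDR
  alternatives are deliberately absent from the validated surface.
* The adaptive Modk weighting is a documented stand-in, not the original
  (unpublished) update rule.
* Accuracy figures from the reference study (78% tree accuracy, 901
  selected genes, 11 clusters, per-leaf accuracies, 84% inter-method
  agreement) are data-dependent properties of an unavailable cohort;
  they parameterize defaults and report formats here but are not
  reproduction targets.
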