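# endotree

Data-driven discovery of disease **endotypes** — mechanistically distinct
subtypes of a complex disease — from cohorts that pair bulk blood gene
expression with continuous clinical/demographic covariates and
categorical disease-status indicators. The package was built around a
childhood-asthma case study (~146 labeled subjects, ~1,300 variable
genes, 81 covariates) but every stage is parameterized and runs on any
cohort in the same three-table shape.

## The method

Given an expression matrix `X` (genes x subjects, positive intensities),
a covariate table `C` (subjects x covariates), and a binary disease
label `y`, the multi-step pipeline is:

1. **Preprocess** — per-gene linear sex adjustment (residuals + grand
   mean), IQR filter (keep genes with `Q3 - Q1 > 2000` intensity units),
   log2 transform.
2. **Screen** — Pearson `r[c, g]` for every covariate-gene pair; gene
   `g` is kept when `min_c p(c, g) < alpha / m` (Bonferroni across the
   `m` covariates, `0.05 / 81 ~ 0.0006`), with `p` from
   `t = r sqrt(n-2) / sqrt(1-r^2)`, df `n-2`.
3. **Cluster** — complete-linkage hierarchical clustering of genes by
   their `|r|` profiles; cut into `k` clusters (default 11), named
   `A`, `B`, ...
4. **Metagenes** — per-cluster PCA (centered, SVD-based); every
   component with variance fraction >= 5% becomes a metagene `F-2` =
   "second PC of cluster F".
5. **Tree** — greedy information-gain decision tree on metagene scores,
   split rule `score <= threshold`, minimum 14 subjects per leaf, stop
   when no admissible split gains more than `gain_epsilon` bits;
   evaluated by segregation accuracy (leaf-majority vote) and a
   10,000-resample bootstrap through the fixed tree.

Baselines in the same package: gene-wise pooled t-tests, single-domain
clustering scored by silhouette / Baker-Hubert Gamma / Hubert-Levine C
over a distance x method x k grid, and the weighted Modk-prototypes
mixed-domain clustering with prototype-z biomarker flagging. A
synthetic-cohort generator with planted endotypes
(`simulate_cohort()`) makes the whole chain testable without any study
data; see the methods vignette (`vignettes/endotype-discovery.Rmd`) for
the generative model and design decisions.

## Worked example

Simulate a default cohort (205 subjects, 146 with known asthma status,
4 planted endotypes) and run the full pipeline:

```r
library(endotree)

sim <- simulate_cohort(synthetic_config(), seed = 1)
res <- run_pipeline(sim$expression, sim$covariates, sim$indicators,
                    sim$truth$sex,
                    pipeline_config(rng_seed = 1, bootstrap_reps = 2000))
res$report
```

```
segregation_report: overall 94.5% (146 subjects), leaves 3 asthmatic / 2 non-asthmatic
 leaf_id      majority  n pct_correct
       1     asthmatic 51   100.00000
       2     asthmatic 14    78.57143
       3     asthmatic 14    78.57143
       4 non_asthmatic 14    85.71429
       5 non_asthmatic 53   100.00000
```

The fitted tree is fully transparent — each branch is a thresholded
metagene, so every leaf traces back to a gene cluster and the covariates
that selected it:

```r
cat(format(res$tree))
```

```
if J-1 <= -0.153203:
  if A-1 <= 0.527316:
    leaf 1 -> asthmatic (asthmatic=51, non_asthmatic=0)
  else:  # A-1 > 0.527316
    leaf 2 -> asthmatic (asthmatic=11, non_asthmatic=3)
else:  # J-1 > -0.153203
  if I-1 <= -0.805129:
    leaf 3 -> asthmatic (asthmatic=11, non_asthmatic=3)
  else:  # I-1 > -0.805129
    if F-2 <= -3.62931:
      leaf 4 -> non_asthmatic (asthmatic=2, non_asthmatic=12)
    else:  # F-2 > -3.62931
      leaf 5 -> non_asthmatic (asthmatic=0, non_asthmatic=53)
```

Reading the numbers: of 146 labeled subjects, 94.5% sit in a leaf whose
majority label matches their own (the planted label noise is 5%, so
~95% is the ceiling); the two 100%-pure leaves (51 + 53 subjects)
recover the two strongest planted endotypes, and the 14-subject leaves
are the minimum-leaf-size boundary isolating noisier groups. The
bootstrap (`res$bootstrap`) gives mean accuracy 0.945, sd 0.019, 95%
interval [0.904, 0.979]. Stage counts live in `res$manifest`
(1500 genes in, 1452 past the IQR filter, 1452 selected, 11 clusters,
40 metagenes, 5 leaves).

## Command line

```sh
inst/cli/endotree simulate --seed 7 --out cohort/
inst/cli/endotree run-all --expr cohort/expression.tsv \
    --cov cohort/covariates.csv --indicators cohort/indicators.csv \
    --sex cohort/sex.csv --seed 7 --out run/
inst/cli/endotree baselines ttest --expr run/expression_log2.tsv \
    --labels cohort/indicators.csv --out ttest/
```

`run-all` writes every intermediate artifact (log2 matrix, correlation
and selection tables, gene clusters, metagene scores/loadings,
`tree.json` / `tree.dot` / `tree.txt`, segregation report, bootstrap
summary) plus `manifest.json` with the config snapshot, seed, and
per-stage counts. Exit codes: 0 success, 2 validation error, 3
computation error.

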