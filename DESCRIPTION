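Package: endotree
Title: Disease Endotype Discovery from Gene Expression, Clinical
    Covariates, and Disease Indicators
Version: 0.1.0
Authors@R: person("MICA", "Methods", email = "endotree@example.org",
    role = c("aut", "cre"))
Description: Implements a multi-step decision-tree method for discovering
    disease endotypes from a cohort with bulk gene expression, continuous
    clinical/demographic covariates, and categorical disease-status
    indicators. The pipeline screens gene-covariate Pearson correlations
    under Bonferroni control, clusters genes by absolute-correlation
    profiles (complete linkage), summarizes each gene cluster into
    metagenes by principal components analysis, and grows an
    information-gain decision tree over metagene scores with a
    minimum-leaf-size constraint, evaluated by resubstitution and
    bootstrap segregation accuracy. Comparison baselines (gene-wise
    two-sample t-tests, single-domain clustering scored by internal
    validity indices, and weighted Modk-prototypes mixed-domain
    clustering) and a synthetic-cohort generator with planted endotypes
    are included so every stage is testable without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
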