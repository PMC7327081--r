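Package: coexstage
Title: Cancer Staging from Single-Sample Co-Expression Network Perturbation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents a single tumour sample by how it perturbs four
    stage-specific gene co-expression networks and classifies its stage from
    the concatenated perturbation vectors. Stage networks are built from
    Pearson correlations with t-based significance over stage-stratified
    reference samples; differentially expressed genes are selected with
    fold-change and p-value cutoffs and variance-balanced across stages.
    Includes a gene-pair hypergeometric pathway-enrichment statistic and
    stage-evolution summaries (persistent, disappearing and emergent
    pathways), a latent-factor simulator of stage-stratified expression with
    planted co-expression modules, and the full split/train/test evaluation
    protocol with per-stage sensitivity, specificity, accuracy and Cohen's
    kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    ranger,
    testthat (>= 3.0.0),
    withr,
    xgboost,
    yaml
Config/testthat/edition: 3
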