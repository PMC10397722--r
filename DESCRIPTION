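Package: orthotype
Title: Cross-Species Tumor-Type Classification on One-to-One Ortholog
    Expression Features
Version: 0.1.0
Authors@R:
    person("Ortholog", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonizes human and canine bulk RNA-seq expression matrices onto
    a shared feature space of protein-coding one-to-one orthologs, trains
    tumor-type classifiers (a 1D convolutional neural network plus random
    forest and multinomial logistic regression baselines) on one species and
    evaluates their transfer to the other with support-weighted multiclass
    metrics. Includes the supporting analyses: unit conversions between raw
    counts, FPKM-UQ and TPM, single-sample gene set enrichment (ssGSEA) with
    a permutation false-discovery-rate procedure, highly-variable-gene
    selection, gene-set intersection tables, and a synthetic two-species
    negative-binomial cohort simulator that provides ground truth for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    matrixStats,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
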