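Package: mirmint
Title: Integrated miRNA-mRNA Differential Expression, Target Enrichment
    and Constrained Graphical-Model Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for paired pre/post expression studies
    that profiles both the transcriptome and the miRNome. Provides
    quantile normalization and a negative-control detection filter,
    empirical-Bayes moderated paired/unpaired differential expression,
    PCA group separation with a Monte-Carlo permutation test, per-miRNA
    target enrichment among anticorrelated differentially expressed
    genes (hypergeometric test and its rank-based generalization),
    validation of candidate miRNA-target networks on independent cohorts
    with zero-constrained graphical lasso models, cross-validated
    prediction and a random-gene permutation null, protein-interaction
    first-neighbour subnetworks with topology statistics and power-law
    degree fits, and a read-stack heuristic that excises and screens
    putative miRNA precursors from genome-mapped small-RNA reads. A
    synthetic-study generator with planted regulators, cohort structure
    and read pileups supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
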