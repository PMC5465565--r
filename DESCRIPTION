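Package: coexRank
Title: Guilt-by-Association Candidate Gene Prioritisation Across
    Expression Datasets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritises candidate disease genes by their co-expression with
    known disease genes across one or more expression datasets. Correlations
    are Pearson correlations weighted by the inverse of the number of samples
    each donor contributes, the prioritisation cutoff is calibrated from a
    permutation null of random gene sets, and evidence is combined across
    datasets by consensus counting. Includes two dataset-cleaning strategies
    (background correction with quantile normalisation, and removal of
    unwanted variation with negative-control genes and ridge regularisation),
    stratification of samples into fifteen developmental periods of the human
    brain, partial and per-period correlation networks, a leave-one-out
    cross-validation benchmarking harness, and a synthetic multi-dataset
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
biocViews: GeneExpression, Network, GraphAndNetwork, BatchEffect,
    Normalization, GenePrediction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
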