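Package: phenoprop
Title: Phenomic Proportions of Interspecific Hybrids from Image-Based
    Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies what fraction of an interspecific hybrid's
    measurable phenotype is attributable to each parental accession.
    Provides ImageJ-compatible seed and pod morphometry (maximum-entropy
    and Huang thresholding, connected-component regions of interest,
    moment ellipses, Feret calipers, corner-corrected perimeters),
    synthetic phenotype-panel and image generators with known ground
    truth, k-nearest-neighbour outlier screening and 0-1 standardization,
    principal-component contribution weighting, random-forest
    classification with out-of-bag error and confusion-matrix phenomic
    proportion estimation, and heteroscedastic multivariate group
    comparison via the modified ANOVA-type statistic (MATS) with
    parametric-bootstrap inference and pairwise post-hoc contrasts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    randomForest,
    png,
    tiff,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
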