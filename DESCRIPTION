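Package: msiclass
Title: Microsatellite Instability Classification from Tumor Mutation
    Annotation Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies tumors as microsatellite stable (MSS) or
    microsatellite instability high (MSI-H) from somatic mutation
    annotation format (MAF) files produced by paired tumor-normal exome
    sequencing. Mutations are tagged for overlap with simple-sequence
    repeats (UCSC simpleRepeat track, repeat unit <= 5 bp), summarized
    into 22 per-megabase mutational-load features, and classified with a
    standardize + radial-basis-function support vector machine tuned by
    grid search with stratified 10-fold cross-validation. Includes the
    full evaluation suite (sensitivity, specificity, precision,
    accuracy, G-mean, F1, ROC and precision-recall curves), per-feature
    Wilcoxon rank-sum comparisons, random-forest feature importance,
    and a synthetic-cohort simulator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
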