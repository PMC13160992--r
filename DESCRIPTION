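Package: ssrOrigin
Title: Microsatellite-Based Biogeographic Origin Inference for Plant Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects simple sequence repeats (SSRs) in per-sample consensus
    genomes that share one reference coordinate frame, encodes them as binary
    presence/absence markers keyed by (locus, motif, repeat count), and infers
    the geographic origin of samples from those markers. Implements four
    feature-selection strategies, including a group-wise conserved SSR filter
    and an L1-regularised one-vs-rest logistic (Lasso) selector with its
    combined cross-entropy plus L1 loss; a classifier benchmarking harness
    with step-1 recursive feature elimination, leave-one-out cross-validated
    learning curves over replicates and mean confusion matrices; and
    Jaccard-distance principal coordinate analysis and UPGMA clustering.
    Ships a synthetic-data generator that plants group-conserved repeat
    structure into feature tables or full FASTA/GFF3 sample sets so that the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    glmnet,
    e1071,
    ranger,
    xgboost,
    ape,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Genetics, Classification, Clustering, FeatureExtraction,
    SequenceMatching
RoxygenNote: 7.3.3
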