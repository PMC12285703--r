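Package: neuroprint
Title: Twin Heritability and Transcriptomic Decoding of Neurophysiological
    Brain-Fingerprints
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the genetic basis of individual variability in
    parcellated neurophysiological power spectra ("brain-fingerprints").
    Implements individual differentiation and twin-pair matching from spectral
    profiles, intraclass-correlation saliency maps with twin-aware
    subsampling, Falconer twin heritability with permutation significance,
    spatial-autocorrelation-preserving spin permutations (Hungarian
    reassignment of rotated parcel centroids), partial least squares
    correlation between cortical gene expression and differentiation maps
    with spin significance, bootstrap and distance-based cross-validation,
    cell-type gene-set permutation enrichment, and developmental
    gene-score trajectory analysis. A synthetic-data generator plants known
    twin covariance structure, spatially autocorrelated expression gradients,
    cell-type enrichment and developmental slopes, so that every stage of the
    pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    clue,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, GeneExpression, Transcriptomics
RoxygenNote: 7.3.3
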