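Package: volnet
Title: Integrative Transcriptome-Volatilome Correlation Network Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating fruit volatile (aroma) profiles to gene
    expression measured on two-channel microarrays across ripening stages.
    Implements spot filtering and MA-lowess normalization for two-channel
    intensities, all-pairs Pearson correlation between gene and volatile
    log2 profiles, complete-linkage hierarchical clustering on correlation
    distance with joint gene+volatile co-clustering, a permutation-based
    SAM-style differential expression test with q-values, sample-space PCA,
    thresholded correlation networks with degree/topology and sub-cluster
    analysis, multi-evidence candidate-gene selection, delta-delta-Ct qPCR
    validation, and a coupled synthetic-data generator with planted ground
    truth for recovery benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
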