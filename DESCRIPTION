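Package: devocomp
Title: Cross-Species Comparative Developmental Transcriptomics
Version: 0.1.0
Authors@R: person("Devocomp", "Maintainers", email = "devocomp@example.org",
    role = c("aut", "cre"))
Description: Tools to compare developmental gene-expression time courses
    across species. Implements soft (fuzzy c-means) clustering of stage
    series with elbow-based selection of the cluster number, orthogroup
    overlap tests between co-expression clusters with a quadrant
    relative-similarity statistic for detecting heterochronic shifts,
    Jensen-Shannon divergence stage matching with bootstrap confidence
    estimates and gene-wise similarity-driver extraction, transcription
    factor class and phylostratum enrichment analytics, and a synthetic
    multi-species data generator with planted cluster, heterochrony and
    annotation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
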