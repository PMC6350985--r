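Package: glicistrome
Title: Identification and Integration of GLI1/GLI2 Binding Regions in
    Neoplastic Chondrocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for characterising the
    GLI1/GLI2 cistrome in neoplastic chondrocytes from ChIP-seq style
    coverage data. Provides library-size normalisation and IgG control
    subtraction of coverage tracks, bandwidth-based enrichment-region
    detection with summit calling, three-criteria peak selection
    (intensity above mean plus one standard deviation, overlap with
    conserved elements, cross-fraction co-occupancy), TRANSFAC
    MATCH-style matrix-similarity motif scanning, interval set algebra
    for co-occupancy partitions (G1-only/G2-only/co-occupied), CTCF
    co-localisation, human-mouse conserved binding-region binning,
    differential-expression calling with gene-neighbourhood assignment of
    binding regions, and the delta-delta-Ct qPCR fold-change computation.
    A synthetic-data module generates every input with known ground truth
    (genomes, planted motifs, planted coverage peaks, planted
    differential expression, region sets with controlled co-occupancy)
    so the whole pipeline is exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
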