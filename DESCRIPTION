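Package: LightSeqKit
Title: Simulation, Demultiplexing and Quantification of Light-Directed
    Spatially Barcoded Sequencing Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and processing sequencing libraries built
    by light-directed in situ DNA barcoding of cDNA. Provides photomask
    rasterization with morphological erosion and error-diffusion dithering,
    a Gaussian light-scatter dose model, a synthetic tissue and read
    simulator with per-read ground truth, fixed-layout read parsing with
    exact-match barcode demultiplexing, deterministic transcript assignment
    with Smith-Waterman rescue of unmapped reads, directional-adjacency UMI
    deduplication with saturation guarding, TPM/RPKM normalization,
    per-unit-area UMI yields and arclength-based cell-count estimation, and
    benchmarking utilities (species discrimination, pseudo-bulk pooling,
    smFISH-anchored sensitivity, layer marker logic, gene body coverage,
    chimeric pair rates and replicate correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    mgcv,
    optparse
Config/testthat/edition: 3
biocViews: Software, Transcriptomics, Spatial, Sequencing, Preprocessing
RoxygenNote: 7.3.3
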