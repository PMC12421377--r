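Package: pasbind
Title: Binding Affinity and Genomic Frequency of Polyadenylation Signal Hexamers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the recognition of polyadenylation signal
    (PAS) hexamers by the mammalian polyadenylation specificity factor (mPSF).
    Implements the exact ternary-equilibrium (cubic mass-balance) solution for
    competitive binding, dissociation-constant estimation from replicated
    fluorescence-anisotropy titrations by nonlinear least squares, simulation
    of direct and competition assay designs, a census of annotated PAS
    hexamers from GFF3 or GenBank genome annotation stratified by signal
    position on the transcript, hexamer variant classification by Hamming
    distance, fold-change ratio tables, and the frequency-versus-affinity
    log-log correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
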