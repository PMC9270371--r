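Package: xlfdr
Title: Experimentally Validated FDR for Crosslinking Mass Spectrometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ground-truth validation of crosslink search-engine results
    against a grouped synthetic peptide library. Peptides carrying exactly
    one reactive residue are crosslinked in small groups, so any reported
    link joining peptides of different groups, or involving a peptide that
    was never synthesized, is a known false positive. The package reads
    heterogeneous search-engine exports through user-auditable column-map
    dialects, normalizes them to a canonical crosslink record model,
    computes the experimentally validated false discovery rate at CSM or
    unique-residue-pair level, finds post-score cutoffs achieving a target
    real FDR, compares identifications across engines and replicates with
    per-region FDR, and analyses physicochemical properties and sequence
    motifs of linearized crosslinks. A library and search-result simulator
    with planted ground truth makes the whole pipeline testable without
    any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
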