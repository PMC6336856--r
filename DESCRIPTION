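Package: spacerhost
Title: CRISPR Spacer-Based Host Assignment for Small Circular ssDNA Viruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns small circular Rep-encoding single-stranded DNA (CRESS-DNA)
    viruses to candidate prokaryotic hosts through CRISPR spacer evidence.
    Provides CRISPR repeat-array detection with leader calling, a semi-global
    ("glocal") affine-gap aligner in which the whole spacer is aligned against a
    local region of a circular viral genome, empirical E-value calibration
    against random sequence, array-level combined significance, protospacer
    adjacent motif (PAM) discovery from flanking-sequence information content,
    strand-targeting and stop-codon usage statistics, and projection of
    protospacers onto an averaged archetype genome. Includes seeded generators
    for synthetic host and virus genomes with planted ground truth used to
    validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
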