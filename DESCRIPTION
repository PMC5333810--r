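Package: lophopax
Title: Pax Gene Family Identification and Classification for Lophotrochozoan Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the Pax-defining domains (128-residue paired domain with
    its PAI and RED subdomains, octapeptide motif, paired-type homeodomain)
    in lophotrochozoan protein sequences, scans family-diagnostic consensus
    motifs written in bracket notation, and classifies sequences into the six
    lophotrochozoan Pax subfamilies (Pax1/9, Pax2/5/8, Pax3/7, Pax4/6,
    Pax-beta, PoxNeuro) by domain architecture. Also provides Gblocks-style
    alignment block filtering, neighbor-joining trees with bootstrap support
    and polytomy collapsing, family monophyly reports, and a seeded synthetic
    Pax-like protein generator for benchmarking every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
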