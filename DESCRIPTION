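Package: redchip
Title: Protein-Centric RNA-DNA Contact Analysis for Bridge-Adapter
    Proximity Ligation Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing RNA-DNA proximity ligation libraries that
    were immunoprecipitated against a chromatin protein (RedChIP-style
    experiments). Paired-end reads are deconvolved into a short genomic DNA
    tag and an RNA-derived part by locating a bridge adapter, parts are
    mapped and paired into RNA-DNA contact tables, and cis- and trans-acting
    RNAs enriched at protein-occupied sites are identified by IP/input
    fold-change analysis with chromatin-state annotation, peak metaprofiles
    and nonparametric group tests. A fully synthetic experiment simulator
    with ground-truth tables makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
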