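Package: e2fdp
Title: E2F/DP Gene-Family Analysis: Promoter Targets, Coexpression
    Networks, and Duplication Dating
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for plant E2F/DP transcription-factor
    family surveys. Classifies proteins into E2F, DP and DEL groups from
    domain architecture; extracts strand-aware promoter windows and scans
    them for the E2FAT binding site (TTTCCCGCC) and a configurable
    cis-regulatory element dictionary; infers an evidence-gated
    coexpression network (binding site in the target promoter plus a
    Pearson correlation threshold); computes Nei-Gojobori (1986) Ka/Ks on
    paralogous coding-sequence pairs and dates duplication events via
    T = Ks/(2*lambda); performs hypergeometric GO over-representation with
    Benjamini-Hochberg FDR; and provides qRT-PCR 2^-ddCt and log2-FPKM
    transforms. A seeded synthetic-data generator with exact ground truth
    makes every stage testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
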