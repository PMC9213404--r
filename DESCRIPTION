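Package: nrltr
Title: Detection of Non-Reference Endogenous Retrovirus LTR Insertions from
    Paired-End Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a discovery pipeline for
    non-reference porcine endogenous retrovirus (PERV) long terminal repeat
    (LTR) insertions. From paired-end alignments and an LTR element library it
    classifies read pairs, collects discordant/split-read anchor evidence,
    clusters anchors into candidate insertion breakpoints, detects 4-5 bp
    target site duplications (TSDs) from soft-clip stacks, assembles junction
    contigs by greedy overlap-layout-consensus, reconstructs the inserted LTR
    as the TSD-to-TSD region, and classifies reconstructed LTRs by U3
    tandem-repeat structure (subtypes A1/A2/B1/B2/B3), Kimura three-parameter
    distances and neighbor joining. A synthetic-data module simulates
    reference genomes, element libraries, donor genomes with TSD-flanked
    insertions and error-free or noisy 150-bp paired-end reads with truth
    alignments, so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
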