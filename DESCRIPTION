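Package: metashot
Title: Species-Level Taxonomic Attribution of Short Metagenomic Shotgun Reads
Version: 0.1.0
Authors@R: person("Metashot", "Developers", email = "metashot@example.org",
    role = c("aut", "cre"))
Description: Classifies short shotgun metagenomic reads to bacterial and
    archaeal species by alignment against a concatenated reference holding
    one representative strain per species. Provides a reference-construction
    tool (organism-name parsing, earliest-strain selection, include/exclude
    filtering), a seeded mock-community read simulator with a uniform
    substitution-error model, a built-in ungapped k-mismatch aligner plus
    SAM/BAM import and an external-aligner adapter, per-species read counting
    with a detection threshold, decoy-based contaminant read removal,
    read-placement statistics (coverage profiles, the exact no-overlap
    probability for uniformly placed reads, feature length and abundance
    estimation, a localized-hits false-positive flag), detection and
    read-assignment accuracy scoring against simulation truth, and a
    reproducible end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
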