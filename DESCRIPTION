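Package: fgarray
Title: Functional Gene Array Probe Design and Hybridization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of highly specific 50-mer oligonucleotide probes for
    functional gene arrays, and analysis of the resulting hybridization
    signals. Sequence-specific and group-specific probes are screened
    against nontarget sequence pools under joint criteria on ungapped
    sequence identity, longest continuous sequence stretch, and
    nearest-neighbor duplex free energy. The package also constructs
    perfect-match/mismatch (PM/MM) control pairs, assembles array layouts
    with control classes, simulates community hybridizations with
    log-linear dose response, GC-dependent efficiency and
    divergence-dependent cross-hybridization, and provides the downstream
    analysis layer: SNR-based positive calling, reference-standard
    normalization, log-log quantitation fits, and community statistics
    (richness, Shannon diversity, evenness, relative-difference tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
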