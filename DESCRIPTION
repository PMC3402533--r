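Package: isrtyper
Title: Isolate Fingerprinting by 16S-23S Ribosomal Interspacer Sizing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterizing cultured bacterial isolates by
    capillary-electrophoresis sizing of 16S-23S ribosomal interspacer (ISR)
    amplicons. Synthesizes two-channel electropherograms from a packaged
    phylotype panel, calls peaks, calibrates migration against a 23-fragment
    internal size standard with a monotone interpolant, classifies major and
    minor amplicons into isolate fingerprints, groups isolates by
    tolerance-based fingerprint matching (including interval-preserving
    matching for linked dual-peak organisms), propagates taxonomic labels
    from a sequenced subset to unsequenced isolates, and scores acid and
    hydrogen peroxide production phenotypes including the double-strong
    probiotic-candidate criterion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
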