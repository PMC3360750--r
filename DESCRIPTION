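Package: efhandscan
Title: EF-Hand and IQ Motif Scanning with Calcium-Binding Affinity Tiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects canonical EF-hand motifs (29-residue helix-loop-helix
    units with a 12-residue calcium-coordination loop) and IQ motifs in
    protein sequences, builds a consensus profile from reference calmodulin
    calcium-binding loops, and classifies each detected loop into
    strong/medium/low calcium-binding affinity tiers by identity at the five
    critical coordination positions. Includes proteome-level survey reports
    (EF-hand count histogram, pairing annotation), a global-alignment percent
    identity utility, and a seeded synthetic proteome generator with ground
    truth for benchmarking scanner sensitivity, tier recovery and false
    positive rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SequenceMatching, MotifDiscovery, Proteomics
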