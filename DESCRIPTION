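Package: PepDigest
Title: In Silico Proteolysis and Bioactive Peptide Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exhaustive single-protease in silico digestion of protein
    sequences under configurable cleavage-specificity rules (built-in
    approximations for papain, ficin and stem bromelain), exact matching of
    released peptides against a bioactive-peptide activity database,
    per-activity profiling with summary tables and heatmap matrices, and
    score-threshold classification of externally scored peptides. Includes a
    synthetic-data generator with analytically known ground truth so every
    pipeline stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
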