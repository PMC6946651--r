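Package: camelscan
Title: Introgression Scanning and Population-Genomic Inference for Camelid
    Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for multi-population variant panels:
    variant filtering and quality summaries, windowed nucleotide diversity,
    Watterson's theta and Weir-Cockerham Fst, identity-by-state distances
    with classical multidimensional scaling, Patterson's D and the
    window-local f_d introgression statistic with block-jackknife Z-scores,
    F3/F4 admixture tests, masking of introgressed windows, and Fst-based
    neighbor-joining phylogenies with window-resampling bootstrap support.
    Includes a Balding-Nichols synthetic-data generator with known
    demographic truth (drift tree, admixture pulses, introgression tracks)
    so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
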