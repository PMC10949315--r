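Package: asparascan
Title: Comparative Genomics and Biochemistry of Short-Chain Bacterial
    L-Asparaginases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for surveying bacterial genomes for
    L-asparaginase genes and characterising the short-chain (scASNase)
    family: six-frame translated homology search with Karlin-Altschul
    E-values and open-reading-frame extraction, length-based family
    partitioning, CLANS-style similarity-graph clustering and 2-D
    embedding, localization-aware per-species co-occurrence statistics,
    greedy identity clustering with Shannon conservation profiling and a
    Levenshtein median-string consensus, Michaelis-Menten and
    substrate-inhibition kinetics fitting (Lineweaver-Burk and nonlinear
    least squares), and Kabsch C-alpha superposition of crystal
    structures. Includes seeded synthetic-data generators with
    machine-readable truth tables so every stage is testable without
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Biostrings,
    bio3d,
    igraph,
    minpack.lm,
    methods,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
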