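Package: dsbphos
Title: Calling DNA Break-Dependent Phosphorylation Sites from
    Two-Condition Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for identifying phosphorylation sites that
    depend on programmed meiotic DNA double-strand breaks from replicated
    two-condition (break-proficient SPO11 versus catalytically dead
    spo11-YF) label-free phosphoproteomics acquired by both data-dependent
    (DDA) and data-independent (DIA) acquisition. Combines a quantitative
    arm (parts-per-million normalisation, log2 transform, empirical-Bayes
    moderated two-group test with Benjamini-Hochberg control) with a
    qualitative presence/absence arm that exploits intensity-dependent
    missingness, merges site calls across acquisition methods, and provides
    downstream sequence analyses: kinase consensus classification (S/TQ,
    RxxS/T, RxxTQE), iterative motif-x style motif extraction, in-silico
    tryptic digestion and detectability annotation, site proximity
    clustering, disorder-region overlap, and a protein-level bootstrap
    set-shift test. Ships a synthetic-study generator with planted ground
    truth and missing-not-at-random dropout so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
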