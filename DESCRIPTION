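Package: domainage
Title: Phylostratigraphic Dating and Evolutionary Rate Analysis of Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying recently emerged protein domains. Assigns
    phylogenetic age classes (Mammalian, Vertebrate, Metazoan, Eukarya) to
    domain types and proteins from phyletic presence/absence profiles over
    ranked species clades; parses domain architectures, classifies young-vs-old
    domain arrangement scenarios (gain into an existing protein, mutual
    dependence, fusion, complex) and tests for positional bias of young
    domains; estimates per-domain-region dN/dS from pairwise codon alignments
    with Nei-Gojobori (1986) counting and Jukes-Cantor correction, and compares
    rates between age classes and between domains sharing a protein. A seeded
    synthetic-data generator with a ground-truth ledger makes every stage
    testable without external genome resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    seqinr,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
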