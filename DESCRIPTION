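Package: mrmkit
Title: Design of MRM/SRM Transition Lists from Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns protein sequences into candidate transitions for multiple
    reaction monitoring (MRM/SRM) on triple-quadrupole mass spectrometers.
    Provides in silico digestion with six protease rule sets (trypsin,
    chymotrypsin, AspN, GluC, LysC, ArgC), peptide filtering by length and
    residue composition, monoisotopic precursor and singly charged b-/y-ion
    m/z computation, proteotypic uniqueness checking by exact substring scan
    against a background proteome, and discovery of variant-bearing peptides
    from a single-residue substitution table. Includes a seeded synthetic
    proteome generator with a ground-truth manifest, CSV/FASTA readers and
    writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
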