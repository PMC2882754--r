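Package: tailscreen
Title: Endocytic Sorting-Motif Scanning and Reporter-Screen Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying short linear sorting signals in the
    cytoplasmic tails of single-pass membrane proteins. Provides a
    positional pattern mini-language and scanner for endocytic motifs
    (YXXphi, acidic dileucine, FXNPXY, YXXXphiN, and the C-terminally
    anchored DXXLL and KKXX signals), topology-aware extraction of
    cytoplasmic tails from type I and type II transmembrane protein
    records, and a motif presence/co-occurrence census over tail sets.
    Also includes simulators for construction of a random-tail reporter
    library (restriction digestion, size selection, ligation and
    translation in the reporter vector context) and for a two-colour
    antibody-uptake flow-cytometry internalization screen, plus seeded
    generators of synthetic proteomes and genomes so that every stage of
    the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
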