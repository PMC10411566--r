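Package: lsukit
Title: Chromosome-Scale Synteny Units from BUSCO Marker Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives chromosome-scale synteny units from the BUSCO
    single-copy ortholog table of an anchor genome, maps further genomes
    onto those units by marker identity, classifies chromosome fusions and
    fissions from unit composition, and quantifies intrachromosomal
    rearrangement as breakpoints in marker order together with small
    nonreciprocal transpositions, expressed as counts and per-Mbp rates.
    Ships a seeded karyotype-rearrangement simulator that emits standard
    BUSCO full tables with a complete ground-truth event log, so every
    stage of the pipeline can be validated against known rearrangements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
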