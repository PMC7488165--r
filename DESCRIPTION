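Package: genotracks
Title: Graphical Genotyping on Paired Genetic and Physical Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for graphical genotyping of offspring from crossing
    schemes with one to four parents. Reads tab-delimited genotype tables,
    classifies the parental origin of every marker allele in an individual
    of interest with an eleven-case decision table, lays out markers on
    paired genetic (centiMorgan) and physical (base-pair) chromosome
    tracks, colours introgressed intervals, and anchors markers to
    physical positions by filtering tabular BLAST hits against a
    consensus genetic map. Includes a crossing-scheme simulator with
    known ground truth and deterministic SVG/PNG figure export for
    near-isogenic line introgression and linkage-drag screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
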