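Package: fkhconsensus
Title: Multi-Study Consensus Analysis of Transcription Factor Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates gene-level target calls from multiple chromatin
    immunoprecipitation (ChIP-chip, ChIP-exo, ChEC) studies of a
    transcription factor into a gene-by-study Boolean matrix, and analyses
    the result: Hamming similarity between studies, exclusive (UpSet-style)
    set intersections, k-of-n voting consensus, functional validation of
    consensus targets against deletion and overexpression time-course
    expression responses, cell-cycle-phase distribution and enrichment of
    target genes, shared-target and functional-annotation tallies, and
    regulatory-network edge export. Developed around the budding yeast
    Forkhead transcription factors Fkh1 and Fkh2, but applicable to any
    factor with several Boolean target lists. Includes a seeded synthetic
    data generator that emulates every input table, so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
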