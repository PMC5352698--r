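Package: sphingolibr
Title: In Silico Retention Time and MS/MS Spectral Libraries for Sphingolipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates in silico MS/MS spectral libraries for 21 sphingolipid
    classes (ceramides, hexosylceramides and sphingomyelin) by combinatorial
    enumeration of sphingoid base, fatty acid and head-group building blocks,
    with diagnostic fragment ions derived from hydrogen-rearrangement rules
    for low-energy collision-induced dissociation. Ships a published segmented
    quantitative structure-retention relationship (QSRR) model for
    reverse-phase LC retention-time prediction, a refitting pipeline
    (correlation prefilter and forward stepwise AIC regression), and
    dot-product spectral identification of query MS/MS features against the
    generated library. Libraries round-trip through NIST MSP and
    LipidBlast-style TSV templates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    readr,
    ggplot2,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ChemmineR,
    ChemmineOB
Config/testthat/edition: 3
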