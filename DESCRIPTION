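Package: lditrends
Title: Text-Mining Trends in Laser Desorption/Ionization Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline pipeline for bibliometric analysis of laser
    desorption/ionization (LDI) mass spectrometry literature. Evaluates
    boolean, field-restricted phrase queries against publication corpora
    (Europe PMC record dialect), computes MALDI-matrix co-occurrence
    enrichment statistics against a non-matrix background rate, exports
    VOSviewer corpus/scores/thesaurus files with publication-year and
    citation imputation, and builds molecular-property (logP x molecular
    weight) landscapes from ChEBI-annotated compound mentions, including a
    Wildman-Crippen logP calculator. A seeded synthetic-corpus generator
    with exact ground truth makes every stage testable without network
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
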