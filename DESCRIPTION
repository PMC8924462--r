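Package: crcatlas
Title: Classification and Cohort Statistics for Circulating Rare Cells
    Detected by Immunostaining-FISH
Version: 0.1.0
Authors@R:
    person("CRC", "Atlas Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing per-cell event tables produced by
    subtraction-enrichment immunostaining fluorescence in situ
    hybridisation (SE-iFISH) scanning of peripheral blood. Implements
    chromosome-8 spot-count ploidy calling, WBC-size gating, circulating
    tumor cell (CTC) and tumor-derived endothelial cell (CTEC)
    phenotype predicates, classification of every nucleated event into a
    71-leaf subtype atlas (cell size x chromosome-8 ploidy x
    marker-combination), cluster/microembolus annotation, dual-probe
    (CEP8/CEP12) co-detection summaries with paired probe comparison,
    per-patient aggregation with positivity rates and tie-corrected
    Kruskal-Wallis group tests, and a seeded hurdle negative-binomial
    synthetic cohort generator for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
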