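Package: msatpop
Title: Microsatellite Panel Diversity, Differentiation and Parentage
    Exclusion Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for large-scale microsatellite (STR) parentage-panel
    monitoring in livestock populations: a validated genotype container with
    CSV and Genepop 4.x input/output, a staged quality-control cascade with a
    fully accounted drop ledger, per-locus diversity statistics (observed and
    expected heterozygosity, polymorphic information content, inbreeding
    coefficients), Weir-Cockerham variance-component F-statistics including
    pairwise theta between birth-year cohorts, exact-enumeration parentage and
    identity non-exclusion probabilities, birth-year trend tables, and a
    Balding-Nichols cohort simulator with a ground-truth defect ledger so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
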