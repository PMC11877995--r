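Package: orthoscreen
Title: Reference-Anchored Cross-Species Temporal Co-Expression Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing developmental time-course transcriptomes
    between two species through a shared reference gene. Gene expression
    profiles over ordered developmental stages are normalized (log2 counts
    per million, optionally z-scaled), correlated against a chosen reference
    gene (e.g. mouse Sox9 and zebrafish sox9b) within each species, and
    ortholog pairs exceeding a Pearson correlation threshold in both species
    are retained. The passing gene list is tested for gene-set
    over-representation with an exact hypergeometric upper-tail statistic
    and Benjamini-Hochberg false discovery rate control. A negative-binomial
    two-species time-course simulator with planted correlated modules and
    divergent paralog pairs provides truth-labelled data for calibration and
    testing, and a configurable pipeline driver runs the whole analysis from
    counts (or a simulation block) to screen and enrichment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
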