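Package: cellenrich
Title: Cell-Type Enrichment Analysis for Bulk Brain DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Over-representation analysis of epigenome-wide association study
    (EWAS) hits against cell-type-specific CpG panels built from purified-nuclei
    methylomes of neurons, microglia, oligodendrocytes and astrocyte-enriched
    cells. Provides construction of high-, medium- and low-specificity CpG
    panels from two purified-cell cohorts (median-methylation criteria plus
    mixed-model pairwise contrasts), exact-test enrichment with a conditional
    Haldane-Anscombe odds ratio and Benjamini-Hochberg false discovery rate,
    a probe-matched permutation null, and a pseudo-bulk simulation framework
    (Dirichlet cell mixtures, composition-shift confounding, differentially
    methylated position injection) for validating enrichment behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nlme,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
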