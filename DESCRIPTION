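Package: mirMutImpact
Title: Impact of Somatic Mutations in miRNA Genes on miRNA Biogenesis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for deciding whether a somatic mutation in a
    microRNA gene disrupts miRNA biogenesis. Implements allele-resolved
    comparison of mutant and wild-type reads within a mutated sample (miRNA
    level by Fisher's exact test; isomiR-profile change by chi-square and
    Cramer's V), cohort comparisons of a single mutated sample against
    wild-type samples of the same cancer type (miRNA level, isomiR-profile
    distance, and 5p/3p strand balance; one-sample t test, z-score and IQR
    outlier rules), the nine/ten-class isomiR end-shift taxonomy, eligibility
    filtering, precursor-stability (ddG) aggregation against a pluggable
    folding backend, and a synthetic-cohort generator with injectable effects
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
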