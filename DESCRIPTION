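Package: telosig
Title: Chromosome-Restricted Cell-Type Signature Analysis for Expression Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-dataset harmonization and differential screening of
    expression microarrays restricted to a single chromosome, built around
    the comparison of a focal cell type (lung telocytes observed at two
    culture timepoints) against a panel of other cell types. Provides a
    synthetic-data generator with planted cell-type-specific signatures,
    readers for plain and GEO series-matrix tables, quantile normalization
    and median-polish probe summarization, housekeeping-gene scaling across
    platforms, a signed relative-difference fold statistic with
    multi-threshold differential counting, all-comparison signature
    intersection, hierarchical clustering of samples, hypergeometric
    gene-set over-representation, and a local co-expression network export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
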