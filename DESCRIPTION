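Package: svpatterns
Title: Classification, Clustering and Signature Analysis of Somatic Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for analysing somatic structural variation in cancer
    genomes. Groups breakpoint junctions into clusters and footprints under a
    proximity null model, enumerates the genomic configurations reachable by
    sequential simple rearrangements and matches observed clusters against that
    library, detects templated-insertion cycles, bridges and chains by path
    reconstruction over a copy-number segment graph, tests associations between
    rearrangement classes and genome properties on a 1-kb pixel grid, fits
    three-regime models to junction microhomology spectra, and extracts
    structural-variant signatures by non-negative matrix factorization with a
    hierarchical Dirichlet process backend. Includes a rearrangement simulator
    that emits internally consistent junctions and copy-number profiles with
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
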