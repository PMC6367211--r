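Package: cofunr
Title: Co-Functionality Networks for Genomic-Instability-Associated Genes and
    Single-Cell Copy-Number Aberration Counting
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ranks genes by the association between their expression and a
    per-sample genomic instability score, builds guilt-by-association
    co-functionality networks from functional-likelihood vectors computed
    against gene-set databases, and extracts gene clusters above a
    co-functionality correlation threshold. Also classifies and counts focal
    versus whole-chromosome copy-number aberrations per single cell relative
    to the modal state of a control population, with rank-based group
    comparisons. Includes synthetic-data generators with known planted truth
    for both the expression/network and single-cell copy-number arms of the
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
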