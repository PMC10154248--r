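Package: parabulk
Title: Pseudobulk Double-Difference Expression Analysis for Heterochronic Parabiosis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell transcriptomic cohorts from heterochronic
    parabiosis experiments with six animal arms (unpaired, isochronic and
    heterochronic young and old mice). Provides a seeded negative-binomial
    cohort simulator with planted aging, surgery, rejuvenation and
    aging-acceleration effects; two-round quality control with doublet-cluster
    flagging and rank-sum cluster markers; per-animal pseudobulk aggregation
    with TMM normalization and a negative-binomial quasi-likelihood F test for
    arbitrary animal-type contrasts, including the rejuvenation (RJV) and
    aging-acceleration (AGA) double-difference designs; bidirectional shift
    cataloguing across contrasts; and preranked permutation gene-set
    enrichment, including a curated senescence-signature scan.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
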