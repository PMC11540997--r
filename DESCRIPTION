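Package: oralgut
Title: Shared Amplicon Sequence Variants Between Paired Oral and Gut Microbiota
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paired saliva/stool 16S amplicon cohorts: accounting of
    habitat-exclusive and shared amplicon sequence variants (ASVs),
    within-individual co-detection, abundance directionality of shared ASVs,
    age-group persistence partitions, and the supporting diversity statistics
    (Shannon index, zero-adjusted Bray-Curtis resemblance, ANOSIM permutation
    tests, principal coordinates analysis, non-metric multidimensional scaling,
    and Welch's t-test post-hoc comparisons). Includes a synthetic paired-cohort
    generator with planted cross-habitat shared ASVs and full ground truth, so
    that every pipeline stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
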