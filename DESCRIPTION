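Package: mckat
Title: Multi-Dimensional Copy Number Variant Kernel Association Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kernel association testing for copy number variant (CNV)
    profiles against binary traits. Similarity between two CNVs is the
    product of an interval Jaccard index, a type-agreement score, and a
    dosage term based on the absolute distance of each copy number from
    the diploid reference; per-subject profile similarity aggregates all
    cross pairs within a genomic region into a positive semi-definite
    kernel matrix. Association is assessed by a variance-component score
    test under a logistic null model, with p-values from the distribution
    of a weighted sum of chi-square variables computed by numerical
    inversion of the characteristic function (with a moment-matching
    fallback). Includes genome and cytogenetic-band scans with Bonferroni
    family-wise error control, plot-ready Manhattan/QQ data export, and a
    simulation framework for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
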