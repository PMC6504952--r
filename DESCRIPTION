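Package: twinmeth
Title: Paired Methylome Analysis for Disease-Discordant Monozygotic Twins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for epigenome-wide association analysis in disease-discordant
    monozygotic twin cohorts profiled on methylation arrays and by whole-genome
    bisulfite sequencing. Implements reference-based cell-type deconvolution by
    constrained projection and residual-plus-mean composition adjustment, a
    paired Wilcoxon signed-rank scan for differentially methylated positions
    with suggestive and FDR-based genome-wide thresholds, treatment-subset
    effect scans, within-pair differentially methylated region calling with a
    cohort-outlier rule, an iEVORA-style differential-variability scan
    (Bartlett variance test plus t-test mean filter), a paired-t region caller
    for bisulfite sequencing counts with coverage filtering, paired t-test
    power analysis, and a synthetic twin-cohort generator with a ground-truth
    ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
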