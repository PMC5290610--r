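Package: cpgnonvar
Title: Tissue-Specific Non-Variable CpG Filtering for Illumina Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tissue-specific lists of non-variable CpGs from cohorts of
    Illumina 450K/EPIC beta-value matrices and applies them as a
    confirm-and-remove dimensionality-reduction filter for epigenome-wide
    association studies (EWAS). Provides bead-count and sample-correlation
    quality control, the 10th-90th percentile reference-range variability
    statistic with threshold-based non-variable calling, permutation tests for
    list overlap and genomic-feature enrichment, vectorised per-CpG linear-model
    EWAS with delta-beta effect sizes and Benjamini-Hochberg correction, a
    sub-sampling power experiment, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
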