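Package: sefunnel
Title: Super-Enhancer Dynamics and Cis-Acting lncRNA Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-ordering super-enhancer identification from H3K27ac peak and
    signal tables (peak stitching, TSS exclusion, hockey-stick thresholding),
    classification of super-enhancers as acquired, lost or retained across an
    ordered tumour-progression series with patient-cohort representation
    counts, and a stepwise prioritization funnel that narrows super-enhancer
    associated lncRNAs to potentially cis-acting candidates via fold-change,
    proximity, annotation, patient-correlation and trend filters. Includes
    delta-delta-Ct qPCR quantification, nuclear/cytoplasmic localization
    calls, and seeded synthetic-data generators with planted ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    stats,
    GenomicRanges,
    IRanges,
    S4Vectors,
    generics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
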