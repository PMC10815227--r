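Package: isomirome
Title: Circulating isomiR-ome Biomarker Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening the circulating microRNA landscape, including
    all isomiRs (5'/3' length variants, polymorphic and mixed variants of a
    canonical mature miRNA), for association with a continuous clinical score.
    Implements hemolysis and library-level quality gates, reads-per-million
    normalisation, aggregation of isomiR counts to total-miRNA counts, a dual
    abundance filter, a permutation-calibrated Spearman correlation screen with
    Benjamini-Hochberg correction, ROC-AUC discrimination with DeLong
    confidence intervals, isomiR-versus-parent superiority comparison with
    seed-change annotation, and cholesterol-efflux (reverse cholesterol
    transport) quantification from scintillation counts. A seeded synthetic
    data generator emulates a small plasma small RNA-seq cohort with planted
    score-abundance associations so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
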