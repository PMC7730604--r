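Package: exrte
Title: Survey of Expressed LTR Retrotransposons from RNA-Seq and Genomic
    Coverage Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies expressed LTR retrotransposons (exRTEs) from
    LTRdigest-style annotation and RNA-seq evidence, dates insertions from
    5'/3' LTR divergence under the Kimura two-parameter model, screens
    predicted ORFs for canonical retroelement domains and the CCHC
    zinc-knuckle RNA-binding motif with an empirical false-discovery rate,
    classifies elements by proximity to annotated genes, estimates
    copy-number variation across cultivars with a normalized-coverage
    (ACM) ratio, and tests exRTE versus non-expressed RTE sets with
    Fisher's exact and Wilcoxon rank-sum statistics. Includes a synthetic
    genome simulator with planted ground truth so the whole pipeline can
    be exercised and validated offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
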