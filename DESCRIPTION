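Package: apadetect
Title: Detection of 3'-UTR Alternative Polyadenylation Events from RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 3'-UTR alternative polyadenylation (APA) events between
    two biological conditions from RNA-seq read coverage. Candidate cleavage
    sites come either from polyadenylation-signal hexamers (AATAAA, ATTAAA)
    scanned in genomic sequence or from peaks in 3'-end-seq coverage. Each
    site is scored by the change in the upstream/downstream mean-coverage
    ratio between conditions and a 2x2 chi-square test on the regional depth
    sums. Includes a two-condition coverage simulator with ground-truth APA
    events, ROC/sensitivity/specificity evaluation, validation of predicted
    sites against 3'-end-seq peaks, and coverage / nucleotide-composition
    plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
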