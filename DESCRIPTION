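Package: emtatac
Title: Chromatin Accessibility and Expression Dynamics of Reversible EMT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for analysing chromatin accessibility dynamics across
    an epithelial-mesenchymal transition (EMT) time course and its reversal.
    Implements peak-set merging by centre distance with condition membership
    flags, inter-peak gap and peak-desert statistics, nearest-TSS annotation,
    quantile-normalised peak-score matrices with Pearson correlation, mean and
    differential peak score (MPS/DPS) accessibility-change classification,
    Poisson differential-peak calling, position-weight-matrix motif scanning of
    fixed 50-bp peak windows with hypergeometric enrichment and
    percentage-change dynamics, permutation-based base-pair overlap enrichment
    with length-matched genome-wide shuffling, hypergeometric gene-set overlap,
    and a CDH1-anchored 76-gene EMT transcriptomic score. A seeded synthetic
    data generator plants known ground truth (nested regions, tag-count fold
    effects, motif occurrences, an EMT expression axis) so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomeInfoDb,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
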