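Package: socmethyl
Title: Early-Life Social Experience, DNA Methylation and Stress Physiology
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking early-life social experience to later-life DNA
    methylation and glucocorticoid stress physiology in wild social mammals.
    Implements maternal-care and association-network exposure construction,
    kinship-aware binomial mixed models for count-based epigenome-wide
    association studies (EWAS), empirical-null inflation and bias correction of
    test statistics, cluster-bootstrap mixed-model inference, best linear
    unbiased predictor (BLUP) consolidation of repeated hormone measurements,
    Baron-Kenny mediation with an attenuation criterion, a meet-in-the-middle
    biomarker screen, and a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    jsonlite,
    yaml,
    data.table,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
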