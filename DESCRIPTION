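Package: latentseg
Title: Latent-Space Unsupervised Semantic Segmentation of Multichannel Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised change-point detection for multichannel time series
    via matrix profiles computed on an autoencoder's latent representation
    (LS-USS). Provides the classic z-normalized matrix profile and the
    FLUSS/FLOSS corrected-arc-curve segmentation baselines, the latent-space
    matrix profile with temporal constraints, a memory-bounded batched
    computation and a fully online forward-arc variant, regime-extraction
    algorithms (REA, LREA, LTEA), segmentation scoring metrics, and a
    seeded generator of regime-switching multichannel biosignal-like series
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
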