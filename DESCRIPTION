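Package: somnoflow
Title: Sleep Architecture, Norepinephrine Infraslow Oscillations, LFQ
    Proteomics and Histology Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis toolkit for multimodal sleep neuroscience studies:
    threshold-based vigilance-state scoring of EEG/EMG recordings and
    sleep-architecture statistics; isosbestic (405 nm) correction of
    two-channel fiber-photometry signals, Welch power spectral density of
    infraslow norepinephrine oscillations during NREM sleep and
    prominence-based peak detection; differential analysis of label-free
    quantification (LFQ) proteomics matrices with completeness filtering,
    mixed downshifted-Gaussian/KNN imputation, s0-moderated permutation-FDR
    t-tests and Fisher/Benjamini-Hochberg gene-set enrichment; and histology
    morphometry (size-binned particle analysis and the AQP4 vascular
    polarization index). A synthetic-data module generates inputs with known
    ground truth for every stage so the whole pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    fgsea,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
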