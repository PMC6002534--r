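Package: compactscreen
Title: Quantitative Analysis of In Vivo Cancer Cell Motility Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for image-based in vivo motility screens that
    score metastatic colony morphology. Computes per-colony compactness
    attributes (Gaussian spread of the rotation-averaged intensity profile,
    convex-hull area, and in-hull cell density) from fluorescence images,
    combines them into a composite Compactness Index of Z-scores against a
    scramble-shRNA control reference, and calls significant hits with
    one-way ANOVA and Fisher's LSD comparisons. Also deconvolves shRNA
    identities from miR-30 hairpin amplicon sequencing reads with loop and
    stem validation, computes cell-track velocity and displacement-rate
    (productive migration) statistics and acute-angle frequency
    distributions, and quantifies metastatic burden from Alu qPCR standard
    curves. Ships seeded synthetic-data generators (colony images, hairpin
    reads, persistent random-walk tracks, qPCR tables) with ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    grDevices,
    graphics,
    utils,
    EBImage,
    Biostrings,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
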