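Package: angioquant
Title: Quantification of Endothelial Cell Polarity, Directed Migration and
    Angiogenic Front Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify directed endothelial cell migration and
    polarization from scratch-wound time-lapse experiments, Golgi-nucleus
    orientation in monolayers, tip-cell orientation and filopodia at the
    retinal vascular front, spheroid sprout morphometry, and avascular
    (vaso-obliterated) area fractions in retinal vessel masks. Includes
    seeded synthetic-data generators (biased persistent random walks,
    two-channel monolayer scenes, vascular-front scenes, retina masks)
    with known ground truth so every analysis stage is testable end to
    end, plus group-level statistics (Welch t-tests, two-way ANOVA with
    Bonferroni-adjusted pairwise comparisons) and a reproducible pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
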