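Package: phenoprime
Title: Plate-Based Rosette Phenotyping and Biostimulant Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of top-view multi-well plate assays of
    in-vitro Arabidopsis rosette growth under optimal, osmotic and salt stress
    conditions. Provides a ground-truth simulator (logistic growth curves,
    rendered plate images with label masks, metabolite concentration tables),
    excess-green segmentation of plate images, the five per-plant phenotyping
    traits (growth-curve slope, area under the growth curve, relative growth
    rate, final size, green leaf index), the Plant Biostimulant
    Characterization Index (PBCI) with bootstrap uncertainty, and the
    statistical surface used to screen seed-priming agents: Kruskal-Wallis
    tests against control, per-metabolite ANOVA with Tukey or Duncan post hoc
    comparisons, SVD-based principal component analysis, and Pearson
    correlation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
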