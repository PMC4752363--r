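Package: ovotrait
Title: Eggshell Colorimetry and Phylogenetic Comparative Analysis of
    Eggshell Pigments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies eggshell background colour and maculation from egg
    photographs (Otsu segmentation, circular one-third-area subsampling,
    CIELAB pixel statistics, k-means spot classification), estimates
    phylogenetic signal (Pagel's lambda) in pigment concentrations by
    maximum likelihood, and relates pigment concentrations to life-history
    and nesting-ecology traits with phylogenetic generalized least squares
    and AIC-based multimodel averaging. A synthetic-data generator
    (pure-birth trees, Brownian-motion traits with tunable signal, rendered
    egg images with ground-truth masks) lets every stage of the pipeline be
    exercised and validated against known truth without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
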