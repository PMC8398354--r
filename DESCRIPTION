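Package: benzoqsar
Title: QSAR Modelling of Benzodiazepine GABA-A Receptor Activity from 2D Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-activity relationship (QSAR)
    modelling of benzodiazepine binding at the GABA-A receptor from
    two-dimensional molecular descriptors.  Implements five 2D descriptors
    (Hueckel pi-bond-order sum, Kier molecular flexibility, and three
    VSA-partitioned surface-area descriptors built on Labute-style
    approximate van der Waals surface areas, Gasteiger-Marsili PEOE partial
    charges and Wildman-Crippen atomic logP classes), a fixed published
    five-descriptor activity equation with low/medium/high potency binning
    and a Tanimoto-similarity applicability domain, and a full
    model-building cascade: similarity-based curation, stratified
    train/test splitting, correlation and collinearity descriptor
    selection, partial least squares regression with leave-one-out
    cross-validation, external validation and outlier flagging.  A seeded
    generator of benzodiazepine-like molecule libraries with planted
    activities makes every pipeline stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
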