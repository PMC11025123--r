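Package: evfingerprint
Title: EV Fingerprinting of Single-Vesicle Flow Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deconvolves heterogeneous extracellular-vesicle (EV) populations
    from multiparametric single-particle flow cytometry of lipophilic-dye
    (di-8-ANEPPS) stained samples. Reads and writes FCS 3.x event files,
    asinh-transforms a 20-dimensional dye feature block, embeds events in two
    dimensions with UMAP and calls populations with HDBSCAN, then re-examines
    clusters of interest on the full data with a gradient-boosted classifier.
    Each population is characterized by a relative size proxy (median 488-611
    fluorescence, total fluorescence), membrane order (generalized
    polarization), and dilution-corrected abundance; condition effects are
    quantified as percent-of-control and by a k-nearest-neighbor pairwise
    change detector (T-REX) with DBSCAN hotspot regions. Includes multiplexed
    antibody cargo gating (e.g. CD63/CD81 partitioning), quantitative-range
    quality control on dilution series, and a fully seeded synthetic single-EV
    event simulator with ground-truth population labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    uwot,
    FNN,
    RANN,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
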