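Package: segmapr
Title: Segmental Mapping of Apoptosis and Signaling in the Drosophila Embryonic Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial distribution of apoptotic cells and
    signaling activity within the repeating segments of the Drosophila
    embryonic epidermis. Detected point events (e.g. cleaved-Dcp1 positive
    cells) are mapped onto a normalized segmental coordinate system using
    distances to skeletonized Engrailed stripe landmarks; fluorescence
    intensity profiles are registered to landmark peaks by resampling each
    segment onto a fixed number of bins and averaged across samples with
    standard errors; and a threshold-survival model of segmental EGFR-ligand
    sources predicts banded apoptosis patterns in segmentation mutants. A
    synthetic-embryo image generator with known ground truth makes every
    stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
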