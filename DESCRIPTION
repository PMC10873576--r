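Package: panelpick
Title: Predictive Marker Panel Selection for Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a minimal predictive subset of markers for multiplexed
    spatial proteomics (CODEX, imaging mass cytometry) such that the full
    images of all remaining markers can be predicted from the imaged subset.
    Markers are organised as a directed complete graph whose edge loadings
    start as pairwise L1 image dissimilarities and are refined by the
    validation risk of predictive models; a greedy expected-improvement loop
    grows the observed set until a stopping criterion holds. Supports the
    multi-panel setting in which markers are split across overlapping panels
    and cross-panel loadings are bounded by chained triangle inequalities,
    balanced overlapping panel design from per-marker feature vectors, pixel
    and single-cell evaluation measures, and a latent-factor synthetic image
    generator for end-to-end testing.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
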