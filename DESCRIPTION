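Package: spinequant
Title: Quantification of Dendritic Fluorescence Clusters, Spine
    Morphometry and Protrusion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-quantification toolkit for studies of dendritic spine
    initiation in fluorescence microscopy. Implements brightness-cluster
    analysis of maximum-intensity projections inside skeleton-grown
    observation-path masks, baseline-normalised cluster time series,
    geometric spine retention and stubby/thin/mushroom classification with
    per-class densities, new-protrusion event detection with
    cluster-precedence association, reference-normalised spine/dendrite
    intensity ratios, knock-down relative intensities, Pearson
    colocalization, and a group-comparison dispatcher. A seeded synthetic
    dendrite-image generator provides ground-truthed projections,
    time-lapse movies, spine tables and colocalization channel pairs so
    that every analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    car,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
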