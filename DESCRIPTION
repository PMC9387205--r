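Package: colorcloud
Title: Perceptual Color Encoding of High-Dimensional Data in CIELAB
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes arbitrary high-dimensional data as perceptually meaningful
    colors. Data are reduced to three dimensions (PCA + UMAP, with dedicated
    tracks for single-cell count matrices, dense feature matrices, precomputed
    distance matrices, and already-reduced 3D coordinates) and the resulting
    point cloud is fitted inside the displayable part of CIELAB color space --
    the image of the sRGB cube -- by multi-start Nelder-Mead optimization over
    a seven-parameter similarity transform (translation, rotation, uniform
    scale). Because CIELAB is approximately perceptually uniform, distances
    between the resulting colors reflect distances between the original
    entities, so the colors can carry the data's structure into network,
    map, or scatter visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    Matrix,
    uwot,
    irlba,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    farver,
    quadprog,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
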