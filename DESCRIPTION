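Package: spotclust
Title: Combined-Clustering Segmentation of cDNA Microarray Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete sub-grid processing pipeline for two-channel (Cy3/Cy5)
    cDNA microarray images: automatic contrast enhancement driven by a
    kurtosis-based contrast degree and an edge-sampled background level,
    projection-profile gridding with h-dome filtering and maximum
    between-class-variance thresholding, per-spot foreground segmentation by
    moving k-means clustering OR-combined with k-means plus a circular
    fallback for weak spots, and background-subtracted log-ratio intensity
    extraction on the raw images. Includes a synthetic sub-grid simulator
    with ground truth and the evaluation metrics (correct/marginal/incorrect
    spot taxonomy, pixel-count RMSE, intensity MSE) needed to benchmark
    every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
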