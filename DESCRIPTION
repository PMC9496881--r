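Package: swarmseg
Title: Brain Tumor Segmentation by Particle Swarm Search with a Two-Way
    ANOVA Fitness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-stage segmentation of hyperintense brain lesions from
    co-registered 2-D MRI-like image pairs. Morphological skull-stripping
    removes non-brain structure; particle swarm optimization locates the
    rectangular block that maximizes a two-way fixed-effects analysis of
    variance contrast (MSA/MSE + MSB/MSE) between the diseased image and a
    disease-free reference; K-means clustering (K = 2) of the block's
    intensities yields the tumor mask. Includes one-way and two-way ANOVA
    tables computed from first principles, a sum-of-absolute-differences
    alternative fitness, an exhaustive-search oracle, Dice/Jaccard/
    correlation/RMSE evaluation metrics, and a seeded synthetic phantom
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
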