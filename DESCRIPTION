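Package: cryoraman
Title: Quantitative Raman and Calcium-Imaging Metrics for Cryopreserved Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for low-temperature confocal Raman
    hyperspectral cubes of frozen single cells and for calcium-imaging
    movies of neuronal cultures. Renders per-substance heat maps by band
    integration, restores them by Richardson-Lucy deconvolution with a
    theoretical point spread function, segments cells by thresholding and
    boundary recognition, and computes per-cell cryoinjury metrics:
    intracellular ice area and morphology (chunky vs dispersed), membrane
    partitioning ratio of cryoprotective solutes, Moran's I spatial
    autocorrelation of amide I and cytochrome C signals with
    eight-nearest-neighbour weights, frozen-cell equivalent diameter, and
    the C-H/O-H hydration ratio. Also includes stimulus-locked responder
    classification for dF/F0 calcium traces, viability/recovery/attachment
    rate calculations with Wilson intervals, a group-comparison layer
    (t-test, ANOVA with Bonferroni correction, Kruskal-Wallis), and seeded
    synthetic-data generators with ground truth for every imaging modality
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
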