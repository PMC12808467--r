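Package: seedmsi
Title: Multispectral Seed Imaging Analysis for Wheat Seed Lots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated analysis pipeline for multispectral seed imaging (MSI)
    of cereal seed lots. Provides calibration of overexposed seed regions via the
    CIE L*a*b* a* channel, removal of the blue conveyor-belt background, watershed
    segmentation of touching seeds refined by convex-hull defect splitting with
    Harris corner anchored cut lines, per-seed extraction of eight morphological
    traits and per-band mean spectral reflectance, phenotype export for downstream
    genetic mapping, and the validation statistics used to verify the pipeline
    (object-matched mean IoU, outlier-screened Pearson agreement, Lilliefors
    normality testing, and broad-sense heritability from variance components).
    A synthetic seed-lot renderer with exact ground truth makes the full pipeline
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    nortest,
    optparse,
    png,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
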