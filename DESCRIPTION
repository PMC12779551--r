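Package: neuritescreen
Title: Longitudinal Neurite Phenotyping and Drug-Screen Analytics for
    iPSC-Derived Motor Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for longitudinal live-cell phenotyping of
    reporter-labelled motor neuron cultures: neurite-length quantification
    from fluorescence image fields (background subtraction, multiscale ridge
    enhancement, segmentation, skeletonization), the LD50 neurite-survival
    statistic with its quality-control rules, plate-based drug-screen
    analytics (days of rescue, screen-relative normalization, responder
    classification), calcium-transient detection from ROI fluorescence
    traces, and the accompanying survival, correlation and power statistics.
    Includes synthetic-data generators with known ground truth for plates,
    image fields and calcium traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
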