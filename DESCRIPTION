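Package: rankletRadiomics
Title: Intensity-Invariant Ranklet Texture Radiomics for Binary Tumor
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided diagnosis toolkit for predicting a binary tumor
    genotype (e.g. IDH wild-type versus mutant glioblastoma) from the texture
    of a tumor region of interest on grayscale MRI. Implements an
    orientation-selective ranklet transform that replaces absolute pixel
    values with normalized Wilcoxon rank-sum statistics in [-1, 1], making
    downstream texture features invariant to strictly monotone intensity
    maps (brightness, contrast, gamma across scanners); masked gray-level
    co-occurrence (14 Haralick-type statistics) and gray-level run-length
    (11 classical statistics) feature extraction; stepwise backward feature
    elimination under leave-one-out error with logistic regression, k-nearest
    neighbor and support vector machine classifiers; and a seeded synthetic
    tumor-image generator so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    nortest,
    class,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
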