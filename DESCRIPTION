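Package: histotx
Title: Transcriptomic Correlates of Histology via Convolutional Feature Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Links visual features of histology slide images to gene expression.
    Tiles whole-slide-style RGB images, trains a small convolutional tissue
    classifier, quantifies location-invariant layer/channel activation features,
    screens genome-wide gene-feature Pearson correlations with permutation
    significance and partial-correlation conditional-independence analysis, and
    visualizes features by guided backpropagation and activation maximization.
    Includes a synthetic paired image/expression data generator with planted
    direct, tissue-mediated and null gene-feature structure, plus an
    architecture catalog with exact feature and trainable-parameter counts for
    the standard convolutional network families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    withr
Config/testthat/edition: 3
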