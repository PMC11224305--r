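Package: hsifluor
Title: Hyperspectral Fluorescence Unmixing and Classification of Brain
    Tumor Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, preprocesses, and analyzes hyperspectral
    fluorescence images of 5-ALA labeled brain tumor biopsies. Measured
    emission spectra on a 420-730 nm grid are modeled as non-negative
    linear mixtures of five fluorophore basis spectra (the PpIX634 and
    PpIX620 photo-states of protoporphyrin IX, NADH, lipofuscin, and
    flavins) and unmixed by non-negative least squares into per-pixel
    abundance vectors. The package provides a synthetic biopsy phantom
    generator with an sCMOS-style noise model, the preprocessing chain
    (dark correction, dual-band white-light normalization, tumor
    segmentation, non-overlapping 10x10 block averaging), PCA with
    variance-explained reporting, t-SNE embedding, a pairwise two-sample
    Kolmogorov-Smirnov battery, and a balanced, cross-validated
    classification protocol over random forests, k-nearest neighbors,
    SVMs, multilayer perceptrons, and AdaBoost for tissue type, resection
    margin, WHO grade, and IDH mutation status.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    randomForest,
    e1071,
    rpart,
    pROC,
    Rtsne,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
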