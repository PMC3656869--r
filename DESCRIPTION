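Package: melmark
Title: Marker-Guided Melanoma Cell Classification in Brightfield IHC Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for fully automated, marker-guided pattern recognition of
    melanoma versus non-melanoma cell nuclei in brightfield
    immunohistochemistry (IHC) tissue-microarray core images. Implements
    colour deconvolution of hematoxylin and DAB stains into optical-density
    channels, Melan-A-style marker and tissue mask generation with a
    pigmentation guard, nuclei segmentation with watershed declumping, a
    73-feature morphology/intensity/Haralick/Gabor/granularity catalogue,
    t-test ranked backward feature elimination with a cubic-fit optimum,
    SVM/random-forest/naive-Bayes classifiers with probabilistic outputs,
    and downstream biomarker (Ki67-style) positive-cell-ratio scoring.
    A seeded synthetic histology generator produces Beer-Lambert two-stain
    scenes with known ground truth so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    png
Config/testthat/edition: 3
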