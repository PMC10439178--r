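Package: skinaudit
Title: Auditing Skin Tone Representation in Educational Documents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end auditor for skin tone representation in
    educational materials. Extracts embedded figures from PDF documents
    (or image directories) with page and coordinate provenance, detects
    images containing human skin using a 38-dimensional global
    gradient-orientation histogram plus CIELAB statistics descriptor,
    segments skin pixels with HSV/YCbCr color rules refined by
    morphology, region growing and watershed, classifies skin tone as
    Fitzpatrick I-IV versus V-VI via individual typology angle (ITA)
    thresholds, ensemble classifiers, or an 18-layer residual
    convolutional network, and reports per-document representation
    balance of dark skin tones. Includes a synthetic data generator with
    known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    jpeg,
    jsonlite,
    png,
    pROC,
    randomForest,
    ranger,
    rpart,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
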