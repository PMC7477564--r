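Package: smeargrade
Title: Ordinal Grading of Granulocyte Dysplasia in Bone-Marrow Smear Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing morphological dysplasia of nucleated cells
    in stained bone-marrow smear images, focused on the "decreased granules"
    (DG) neutrophil phenotype graded on a 0-3 ordinal scale. Provides a
    seeded synthetic smear generator with planted granule-density and
    nuclear-lobation signals, a classical cell detector and cropper, an
    imbalance-aware augmentation pipeline (paste-to-field canvas, random
    geometric transforms, rare-label oversampling), a multi-label ordinal
    regressor with a weighted-mean-quartic loss trained by Adam, test-time
    rotation-ensemble inference with category gating, iterative multi-label
    stratified cross-validation, screening metrics (sensitivity,
    specificity, PPV, NPV, accuracy, rank-based AUC), and a
    doctor-in-the-loop label-revision workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    yaml,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
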