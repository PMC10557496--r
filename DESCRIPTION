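Package: DRgrader
Title: Explainable Diabetic Retinopathy Grading from Typed Lesion Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies typed retinal lesions (hemorrhage, hard and soft
    exudate, aneurysm, neovascularization) from polygon annotations of fundus
    photographs, grades each image into the five diabetic-retinopathy severity
    levels with a transparent conjunctive rule set, and renders a
    clinician-readable explanation for every grade. Lesion burden is expressed
    as counts and as area ratios against a circular retina model so that images
    of different resolution and vertically clipped photographs are comparable.
    Includes a from-scratch CART (Gini) decision-tree learner that re-derives
    threshold rules with leaf confidences from labeled feature tables, an
    audit of rule mutual exclusivity and domain coverage, a synthetic
    fundus-image and annotation generator for end-to-end testing, and the
    classical fundus preprocessing chain (crop to retina, resize, CLAHE
    contrast enhancement, green channel, augmentation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    rpart,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'severityRules.R'
    'auditRules.R'
    'cart.R'
    'lesionQuantify.R'
    'io.R'
    'pipeline.R'
    'preprocess.R'
    'show-methods.R'
    'syntheticData.R'
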