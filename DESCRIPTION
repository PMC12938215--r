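Package: SonoCAM
Title: Auditing Grad-CAM Attention of Ultrasound Lymph-Node Station Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for quantitatively auditing where a convolutional
    lymph-node-station classifier looks when it classifies endobronchial
    ultrasound (EBUS) B-mode images. Provides a synthetic sector-scan phantom
    generator with exact per-structure ground-truth masks (hypoechoic nodes,
    anechoic vessels, shadow and reverberation artifacts, multiplicative
    speckle), a patient-wise training harness for an eight-station classifier
    with an AdamW-trained small convolutional backbone, from-scratch
    Grad-CAM reduced to a 7 x 7 activation grid with a 0.9 activation-region
    threshold, max-intensity-cell frequency maps, a four-category annotation
    model with a deterministic mask-overlap oracle and simulated noisy raters,
    majority-rule consensus, percent agreement with Cohen's and Fleiss' kappa
    and Landis-Koch interpretation bands, and per-class, macro, weighted and
    attention-stratified classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    e1071,
    caret
Config/testthat/edition: 3
RoxygenNote: 7.3.3
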