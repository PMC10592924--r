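Package: cryopick
Title: Cryo-EM Particle Picking with an Attention-Gated U-Net and
    Mask-Proposal Postprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end single-particle picking pipeline for cryo-EM
    micrographs: a six-stage contrast-enhancement and denoising chain
    (Gaussian, standard normalization, fast non-local means, adaptive
    Wiener, CLAHE, guided filtering), an attention-gated U-Net that
    segments particles in 1024x1024 micrographs, a scored mask-proposal
    stage with non-maximum suppression and confidence filtering, and a
    mode-based size-consensus postprocessor that emits RELION-style .star
    coordinate files. Includes a seeded synthetic-micrograph generator
    with confounders (ice patches, carbon edges) and particle-level
    evaluation (precision, recall, F1, Dice).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
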