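Package: octfundus
Title: Mean-Value Fundus Projection and Stage-Independent Classification
    of Retinal OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projects segmented optical coherence tomography (OCT) volumes of
    the rodent retina into per-layer mean-value fundus (MVF) images, normalizes
    them with a CLAHE plus Gaussian low-pass illumination-correction chain,
    splits cohorts at the animal level with age-restricted training, trains a
    compact convolutional classifier per retinal layer to separate wild-type
    from transgenic animals, and evaluates both within-age and outside-age
    ("stage-independent") test scenarios with confusion matrices, the four
    standard binary metrics, and per-age error tables. A synthetic cohort
    generator with a plantable, maturity-ramped group effect makes every stage
    of the pipeline exercisable end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
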