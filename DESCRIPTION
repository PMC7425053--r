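Package: bbbopen
Title: Outcome Quantification for Ultrasound-Mediated Blood-Brain Barrier
    Opening Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the outcomes of pulsed focused ultrasound plus
    microbubble blood-brain barrier (BBB) opening experiments in small
    animals: passive-cavitation-detector acoustic emission scoring
    (subharmonic detection against a median noise floor, harmonic increase
    over a pre-injection baseline), contrast-enhanced MRI relative signal
    enhancement between sonicated and contralateral hemispheres,
    semiquantitative histopathology grading of microhemorrhage and edema,
    glial activation densities and hemisphere differences, and a
    dose-response statistical layer (Gompertz nonlinear least squares,
    Kendall tau, exact Fisher, Wilcoxon signed-rank with the Pratt zero
    treatment, and the Jonckheere-Terpstra trend test with exact
    small-sample null distributions).  A seeded synthetic-cohort generator
    provides ground-truth pulse traces, image pairs, and histology
    annotations so the full pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    minpack.lm,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
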