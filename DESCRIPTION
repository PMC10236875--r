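Package: thvcpi
Title: Contact-Pressure Modeling of Conduction Disturbance Risk After
    Self-Expanding Transcatheter Aortic Valve Replacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale, patient-specific modeling of the mechanical
    interaction between self-expanding transcatheter heart valve frames
    (Evolut PRO 23/26/29 mm and Evolut R 34 mm) and the aortic root, aimed
    at predicting post-implant conduction disturbance. Provides parametric
    synthetic aortic-root anatomy, a quasi-static ring-stack frame-wall
    contact solver, the contact pressure index (CPI) and maximum contact
    pressure (CPMax) computed over a membranous-septum region of interest,
    implantation-depth planning, a synthetic cohort generator with clinical
    outcome models, and the diagnostic-accuracy, regression and survival
    statistics used to validate the scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
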