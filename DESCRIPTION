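Package: cranioage
Title: Gestational Age Estimation from 3D Fetal Cranial Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learning-based prediction of fetal gestational age from 3D
    ultrasound volumes of the fetal head. The fetal skull is parametrized by a
    deformable closed subdivision surface fitted to interior-skull edge
    candidates detected with the monogenic-signal feature asymmetry measure.
    Appearance (Haar-like volume-of-interest), local size, and inner head
    circumference features anchored to the fitted surface are mapped to
    gestational age by a regression forest with variance-reduction splitting
    and Gaussian leaves. Includes a synthetic skull-phantom generator with
    known ground truth for end-to-end validation, NIfTI/PLY/CSV/JSON
    interchange, and a command-line pipeline (simulate, fit-surface, train,
    predict, report).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
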