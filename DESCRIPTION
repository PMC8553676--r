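Package: vepacuity
Title: Visual Acuity Estimation from Steady-State Visual Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective visual acuity estimation from steady-state visual
    evoked potential (VEP) recordings to checkerboard stimuli of graded
    check size. Provides artifact rejection, first-harmonic Fourier
    analysis with neighbour-bin noise correction and significance testing,
    construction of spatial-frequency tuning curves, a stepwise heuristic
    that extrapolates the descending limb of the tuning curve to its
    abscissa intercept (the VEP spatial-frequency limit) and converts it
    to decimal/logMAR acuity, a retrainable neural-network acuity
    regressor with a range-of-validity guard, and paired permutation and
    bootstrap statistics for within-participant condition comparisons.
    Includes a synthetic SSVEP cohort generator with known ground truth
    for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
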