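Package: adlkin
Title: Smartwatch Accelerometry Kinematics of Daily-Living Tasks in Frailty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify upper-extremity performance of activities of
    daily living (ADL) from wrist-worn 100 Hz tri-axial accelerometry in
    older adults. Provides a burst-pause synthetic signal generator with
    known ground truth, preprocessing of the acceleration magnitude
    (gravity removal, rectification, local-regression smoothing),
    extraction of nine kinematic parameters covering activity, agility,
    smoothness, energy and intensity, adapted Fried frailty-phenotype
    scoring, and the inferential stage: one-way ANOVAs with Tukey post hoc
    tests and effect sizes, inter-task correlations, a permutation
    multivariate group test, and forward-stepwise multiple linear
    regression of the frailty score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
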