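Package: imprintstat
Title: Learning-Dependent, Predisposition, and Training Side-Effect
    Classification for Filial-Imprinting Biochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for immunoblot densitometry measurements from
    filial-imprinting experiments in the domestic chick. Converts band optical
    densities to relative protein amounts via per-autoradiograph standard-curve
    calibration, scores behavioural preference, removes hatch-batch effects,
    fits a linear mixed-effects regression of protein amount on preference
    score with a random batch intercept, and classifies each protein measure as
    learning-dependent, a predisposition to learn, a training side-effect, or
    no evidence, using intercept comparisons against untrained controls
    (Welch-Satterthwaite) and one-tailed residual-variance-reduction F tests.
    Includes a synthetic-experiment generator emulating the batch-structured
    study design under null, learning, side-effect, and predisposition
    scenarios, and a Monte-Carlo driver for operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
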