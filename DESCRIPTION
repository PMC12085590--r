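Package: socialtouch
Title: Trial-Based Analysis of Neural and Behavioral Responses to Social and Object Touch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured electrophysiology and
    videography recorded during repeated presentations of social (another
    mouse) or non-social (object) facial touch under voluntary or forced
    conditions. Provides peristimulus time histogram construction with
    ISI-baseline z-scoring, unit quality control and cell-type assignment,
    PCA/k-means response clustering with a gap-statistic choice of K,
    stimulus/baseline modulation indices, leave-one-out decision-variable
    ROC preference classification with a permutation null, cross-validated
    population decoding of touch context with shuffle and drift controls,
    a ridge linear encoding model of trial-averaged firing from behavioral
    regressors, and a synthetic session generator with planted ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
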