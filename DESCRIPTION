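Package: adensemble
Title: Imbalance-Aware Ensemble Models for Aortic Dissection Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building auxiliary-diagnosis classifiers on severely
    class-imbalanced clinical tabular data, motivated by early screening of
    aortic dissection (AD). Implements EasyEnsemble (balanced undersampling
    with AdaBoost base learners) and its random-subspace variant
    RS-EasyEnsemble (per-base random feature subspaces with best-half model
    selection and a rounded-average vote), four comparison classifiers
    (linear discriminant analysis, a single-hidden-layer back-propagation
    network, random forest, and a radial-kernel support vector machine),
    univariate index screening from raw cohorts or from published summary
    statistics (Welch and pooled t, Pearson chi-square), stratified
    diagnostic error metrics, and a synthetic cohort generator parameterized
    by published class-conditional summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    randomForest,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
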