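Package: ICAnnotate
Title: Multi-Expert Annotation Aggregation and Automatic Classification
    of EEG Independent Components
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for turning multi-expert annotations of EEG independent
    components (ICs) into machine-learning targets and for classifying ICs
    automatically. Implements two label-aggregation strategies (majority
    vote and probabilistic vote), inter-rater agreement statistics (Cohen's
    and Fleiss' kappa, inter-expert correlation), a spatio-spectral feature
    set for IC topomaps and source time series - including topography
    features that discriminate mu from alpha rhythm and an alpha-band
    amplitude ratio widened for pediatric EEG - and a repeated train/test
    split validation pipeline over three classifier families with
    balance-aware model selection. A seeded synthetic IC and annotation
    generator emulates class-specific topographies and spectra so the whole
    pipeline is testable without real EEG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    e1071,
    xgboost,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'ICAnnotate-package.R'
    'aggregation.R'
    'agreement.R'
    'montage.R'
    'ic-model.R'
    'spectral.R'
    'features.R'
    'models.R'
    'classify.R'
    'io.R'
    'synthetic.R'
    'cli.R'
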