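Package: enoseTransfer
Title: Instance-Based Transfer Learning for Electronic-Nose Pesticide
    Recognition under Domain Shift
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for recognising pesticides in groundwater from
    electronic-nose (e-nose) sensor-array signals when the training and
    deployment data come from different domains. Provides a synthetic
    two-domain generator for 26-sensor response matrices with a calibratable
    source/target distribution shift, five feature-extraction methods
    (Fourier, wavelet, integral, maximum, mean), a per-sample-weighted
    linear support vector machine, a multiclass TrAdaBoost ensemble for
    instance-based transfer, and an experiment harness for feature
    screening, parameter sweeps, method comparison and PCA diagnostics for
    both qualitative (pesticide type) and semi-quantitative (concentration
    level) classification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    cluster,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
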