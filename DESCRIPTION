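Package: fcxai
Title: Explainable Functional-Connectivity Classification with Sparse
    Autoencoders and Remove-And-Retrain Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for explainable classification of
    resting-state fMRI functional connectivity. Simulates two-group ROI
    time-series cohorts with planted connectivity differences and a
    motion-corrupted subpopulation; extracts Fisher-Z connectivity
    features with framewise-displacement filtering; reduces
    dimensionality by SVM recursive feature elimination; trains a
    two-layer stacked sparse autoencoder with a KL-divergence sparsity
    penalty and softmax head under stratified cross-validation;
    computes seven feature-attribution methods (Integrated Gradients,
    LIME, kernel SHAP, DeepLift, DeepLiftShap, GradientShap, Guided
    Backprop); benchmarks them by Remove-And-Retrain; and aggregates
    feature attributions to ranked AAL regions with Brodmann-area
    annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
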