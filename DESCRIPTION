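Package: asyncecg
Title: Acute Myocardial Infarction Detection from Asynchronous Multi-Lead ECGs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects acute myocardial infarction from asynchronous multi-lead
    electrocardiograms such as those recorded sequentially with a smartwatch.
    Implements the limb-lead algebra (Einthoven's law and the Goldberger
    relations) used to derive completely asynchronous lead sets from standard
    12-lead reports, a weight-shared residual 1-D convolutional encoder with
    lead-masked multi-head self-attention trained under random lead masking so
    that a single model serves any lead subset, ROC/PR evaluation with
    matched-specificity operating points and the paired DeLong test, ICD-10
    based cohort labeling rules, and a slot-asynchronous synthetic ECG
    generator with territory-specific ST deviation used as the test and demo
    substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
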