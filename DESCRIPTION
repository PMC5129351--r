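Package: gepqsar
Title: Gene Expression Programming for QSAR Carcinogenicity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evolves symbolic classification rules for the carcinogenic
    potency of aromatic amines from molecular descriptors, using gene
    expression programming (GEP) over Karva-notation chromosomes. Provides
    the full modelling workflow: descriptor-table ingestion with a Pearson
    collinearity filter, reproducible train/test allocation, a generational
    evolutionary loop with the classic GEP operators, a rule-significance
    fitness, screening-test evaluation (sensitivity, specificity, Youden's
    index), a single-hidden-layer perceptron baseline trained by
    backpropagation with early stopping, margin diagnostics, and a
    correlated-Gaussian synthetic descriptor generator with plantable
    decision rules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
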