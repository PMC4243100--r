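Package: resi
Title: Instance-Based Redundant Feature Selection for Binary Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised feature selection for high-dimensional binary
    classification problems such as tumour classification from gene
    expression microarrays.  Implements the RESI forward search, which
    measures redundancy between features by comparing their per-instance
    predictive power (neighbourhood purity and the REMI redundancy measure)
    rather than their numerical similarity, together with the classical
    mutual-information merit functions (MIFS, mRMR, MIFS-U, mIMR/JMI,
    CMIM/IF, CFS) over Fayyad-Irani MDL-discretised features, a synthetic
    expression-data generator with planted relevant, duplicate,
    complementary and irrelevant features, and a stratified repeated
    cross-validation benchmarking harness scored by balanced accuracy with
    paired t-test win/tie/loss summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    rpart,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
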