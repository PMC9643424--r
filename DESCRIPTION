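Package: qclr
Title: Quantum Circuit Learning for Molecular Property Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Variational quantum circuit regression for quantitative
    structure-property relationship (QSPR) modelling on an exact
    statevector simulator. Provides a few-qubit simulator with exact and
    finite-shot Pauli-Z expectation readout, an angle-encoding circuit,
    two variational ansaetze (a layered hardware-efficient circuit and a
    four-qubit MERA), shot-noise-robust training via single-sample
    stochastic gradient descent with the parameter-shift rule, a
    full-batch Nelder-Mead baseline with shot-budget accounting, an
    end-to-end pipeline (PCA, min-max/tanh scaling, R-squared and
    cross-validated Q-squared), and a latent-factor generator for
    QSPR-like benchmark datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
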