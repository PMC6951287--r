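Package: ramanclass
Title: Raman Spectral Preprocessing, DAPC Classification and
    Leave-One-Out Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric classification of Raman spectra of liquid
    samples. Implements a four-step preprocessing chain (wavenumber
    truncation, iterative asymmetric polynomial baseline correction,
    vector normalization, replicate averaging), principal component
    analysis with linear discriminant classification in PC-score space
    (DAPC), grouped leave-one-out validation reporting accuracy,
    sensitivity and specificity versus the number of retained principal
    components, analytic and Monte-Carlo random-chance baselines, a
    synthetic spectrum generator with known ground truth, and a
    command-line interface over delimited-text spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
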