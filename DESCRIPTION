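Package: raschpool
Title: Rasch Item Pool Construction and Adaptive Test Administration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building calibrated item pools for checklist-style
    instruments (such as parent-report vocabulary inventories) and
    administering them adaptively. Implements marginal maximum likelihood
    calibration of Rasch and two-parameter logistic item response models,
    infit/outfit item-fit screening, score-test modification indices,
    simulated-annealing item subset assembly under a spacing-and-fit
    objective, cross-validated Rasch versus 2PL model comparison,
    differential item functioning screening, KR-20 and person-separation
    reliability, and a computerized adaptive testing engine with maximum
    likelihood ability estimation, nearest-difficulty item selection and
    standard-error stopping. A synthetic-data generator emulating a large
    parent-report vocabulary study supports end-to-end validation without
    access to raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
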