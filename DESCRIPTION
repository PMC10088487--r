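Package: passivelp
Title: Passive EEG Assays of Low-Level Language Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two passive-listening EEG assays of low-level language
    processing in clinical populations: mapping of differential phoneme-class
    responses (onset-locked epoching, mass-univariate two-tailed Wilcoxon
    rank-sum tests with Benjamini-Hochberg false-discovery-rate control) and
    natural speech envelope tracking (segmentwise cross-correlation against a
    shuffle-based empirical null). Includes preprocessing (notch and band-pass
    filtering, standardization, artifact masking), equal-subject-weight
    aggregation across trials and subjects, a command-following /
    language-processing categorization tree for disorders-of-consciousness
    cohorts, a calibrated synthetic-data generator, and readers and writers
    for EDF, WAV and delimited annotation and result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
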