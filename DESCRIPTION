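Package: ethnoconcord
Title: Auditing Ethnicity Coding in Episodic Health Records Against a Census Gold Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for auditing the quality of ethnicity coding in episodic
    health-administrative records (primary care, hospital episodes, talking
    therapies, and single-record assets) against a gold-standard census
    source. Provides harmonised 19/18/16-category ethnic vocabularies with a
    5-category collapse, per-person modal and most-recent derivation rules
    with source-specific tie-breaking, sequential reallocation cascades for
    Not Known / Any Other Ethnic Group / Not Stated codes, census-by-source
    concordance tables with agreement, sensitivity and
    positive-predictive-value summaries, statistical disclosure control
    (small-cell suppression and rounding to the nearest five), and a
    synthetic linked-data generator with known misclassification structure
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
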