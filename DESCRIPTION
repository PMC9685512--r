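Package: nursetrace
Title: Infer Nurse-Patient Assignments from EHR Charting Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospectively infers which single bedside nurse was assigned
    to each intensive-care patient during each 12-hour shift, using only the
    timestamped electronic signatures nurses leave when documenting clinical
    assessments and medication administrations. Implements a deterministic
    two-step selection rule (argmax over unique charting times with an
    interval tie-break, then exclusion of the prior shift's primary nurse),
    a six-way outcome categorization, validation against chart-review labels
    with exact binomial confidence intervals and stratified sampling, and a
    synthetic EHR event-stream simulator with ground truth and configurable
    contamination scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
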