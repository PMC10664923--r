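Package: trajmine
Title: Mining Statistically Supported Disease Trajectories from Longitudinal Medical Event Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for extracting temporal disease trajectories from timestamped
    medical event histories (ICD-9/ICD-10 diagnoses and registered treatment
    codes). Ordered event pairs are scored by relative risk estimated through
    repeated stratified sampling of matched comparison groups, bidirectional
    pairs are resolved with an exact binomial directionality test, selected
    pairs are chained into trajectories under patient-support and time-window
    constraints, and trajectories are clustered with a native Markov cluster
    (MCL) implementation on a Jaccard similarity graph. Includes ICD-10
    hierarchy and CCSR vocabulary handling, a synthetic cohort simulator with
    planted causal chains for validation, tabular/GML/CSV result writers, and
    a command-line interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
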