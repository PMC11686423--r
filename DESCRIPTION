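Package: aascore
Title: Analog Accessibility Scoring by Virtual One-Step Analog Enumeration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores compounds by the number of unique, scaffold-preserving
    analogs reachable in a single synthetic step. Input compounds are
    disconnected by single-step retrosynthesis templates, the smallest
    reactant of every round-trip-validated route is replaced by purchasable
    candidates that contain the same extended reaction center and are
    Tanimoto-similar to it, products are rebuilt by forward prediction, and
    survivors of a maximum-common-substructure scaffold filter are counted.
    Ships a deterministic reaction-template backend, a pluggable interface
    for external retrosynthesis and forward-prediction models, a reactant
    database module with curation profiles, fixture generators, and a
    command-line interface with full route-level provenance in its reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
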