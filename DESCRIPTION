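Package: statepop
Title: Conformational State Populations from Inter-Residue Distance Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for converting multi-model structural ensembles into
    per-state inter-residue distance-matrix libraries, estimating
    conformational-state populations from a predicted distance matrix by
    constrained least squares over the state simplex, quantifying state
    discrimination with per-pair one-way ANOVA maps and distance
    distributions, and triaging multi-model virtual-screening predictions
    with a conservative min-aggregate consensus score. A synthetic-data
    module generates every input with known ground truth so parameter
    recovery and selection logic are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
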