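Package: combonull
Title: Null Models for Drug Combination Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reference-effect ("null model") calculations for two-drug
    combination experiments. Implements the Loewe additivity model, the
    Tallarida dose-equivalence model in both orderings together with its
    lower/upper envelope, the Hand model based on summation of
    effect-sensitivity curves, the Bliss independence model and the
    Highest Single Agent (HSA) model, all on four-parameter Hill
    dose-effect curves. Includes Hill curve fitting with BIC-based
    selection against a zero-effect model, isobole extraction and
    convexity diagnostics, synergy/antagonism classification of
    checkerboard assay data, cross-model comparison summaries, handling
    of partial versus full agents, and a synthetic-data generator for
    monotherapy titrations and combination checkerboards with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
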