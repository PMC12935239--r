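Package: dietmcda
Title: Multicriteria Value Measurement for Dietary Substitution Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates additive multi-attribute value models for
    comparing dietary substitution scenarios across health, environmental,
    economic and social criteria. Derives cardinal value scales and swing
    weights from qualitative MACBETH pairwise judgments via linear
    programming, converts scenario performance into partial values through
    piecewise-linear value functions anchored at Neutral (0) and Good (100)
    reference levels, aggregates them into global scores, and probes the
    recommendation with single-weight sensitivity analysis and interval-based
    dominance robustness analysis. Ships a fully worked beef-to-pulses
    substitution case study for Portugal and Denmark, a synthetic model and
    judgment-matrix generator for property testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quadprog,
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
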