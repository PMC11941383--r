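Package: fpromethee
Title: Fuzzy PROMETHEE Outranking Analysis for Technology Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria decision analysis with the fuzzy PROMETHEE I/II
    outranking method. Evaluations and criterion weights may be given as
    5-level linguistic terms backed by triangular fuzzy numbers, which are
    defuzzified with the Yager (centroid) index before the outranking step.
    Provides the six classical preference functions (with Gaussian spreads
    estimated from the data by default), positive/negative/net outranking
    flows, the PROMETHEE I partial preorder, complete net-flow rankings with
    a per-criterion strength/weakness decomposition, weight-change and
    Monte Carlo sensitivity analysis, and a seeded generator of synthetic
    decision matrices shaped like a sequencing-platform selection study
    (15 alternatives, 20 mixed numeric/linguistic criteria).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
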