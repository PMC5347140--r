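Package: moadecon
Title: Dose-Response Deconvolution of Dual PI3K and Microtubule Drug Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to separate a drug's PI3K-inhibitor activity from a
    microtubule-destabilizing activity using cell-panel pharmacology.
    Implements variable-slope logistic dose-response fitting with an
    ambiguity rule, Hill-slope mechanism classification and least-square
    penalty scores across cell-line panels, target-engagement analysis at
    the growth IC50 with therapeutic-window reports, competitive-binding
    Kd derivation from TR-FRET tracer displacement (Cheng-Prusoff),
    microtubule dynamic-instability statistics from kymograph event
    tables, tubulin-polymerization turbidity analysis, high-content
    per-nucleus cytometry summaries (mitotic index, condensed DNA, cell
    cycle gating), and seeded synthetic-data generators that emulate the
    statistical structure of each assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
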