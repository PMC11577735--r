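Package: constru
Title: Conditional Prognostic Biomarker Discovery by Gene-Stratified
    Survival Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers genes whose low/intermediate/high expression tertiles
    condition the prognostic power of a continuous immune score (the
    cytolytic activity score, CYTscore).  For every gene of an expression
    matrix, patients are split into expression tertiles and a multivariable
    Cox proportional-hazards model of the score is fitted within each
    tertile; genes are ranked by a parity score contrasting the score's
    significance and effect size between the lower and upper tertiles,
    filtered by score correlation, and intersected across training cohorts
    to derive UpperT/LowerT candidate sets and the STRATsig stratification
    signature.  Includes signature scoring (mean-log2, sum-of-z,
    difference), tertile-conditional survival evaluation, per-gene survival
    screens with Benjamini-Hochberg control, a synthetic-cohort simulator
    with planted tertile-conditional effects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
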