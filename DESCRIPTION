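Package: fragattain
Title: Fragility Index Attainability for 2x2 Clinical Trial Tables
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the original fragility index (FI) algorithm for
    two-arm trials with binary outcomes, with explicit attainability
    semantics: instead of failing with a generic error when no finite FI
    exists, the algorithm classifies every valid baseline-significant
    2x2 table as attainable, not attainable (with the failure mechanism:
    no legal move, or path exhaustion), or not evaluable. Includes an
    exact two-sided Fisher test engine built on the hypergeometric
    distribution with cached log-factorials, complete enumeration of all
    nondegenerate 2x2 tables over a range of total sample sizes with
    per-N summaries, mechanism and minimum-cell tallies, Spearman
    rank-correlation analysis of predictors of nonattainability, a
    registry of counterexample and published-trial tables, CSV batch
    evaluation, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
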