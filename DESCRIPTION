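Package: wptstrategy
Title: Learning-Strategy Analysis for the Modified Weather Prediction Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing choice behaviour in a modified Weather
    Prediction Task (WPT) with four cues, fourteen cue patterns and a fixed
    100-trial probabilistic design. Implements the canonical task design
    table and its derived quantities, twelve idealised learning-strategy
    response profiles, the normalised least-squares (Gluck) strategy-fit
    score with full-task and 50-trial-block windows, per-pattern and
    per-category performance analyses with repeated-measures statistics and
    effect sizes, and an agent-based synthetic cohort generator so that
    strategy attribution and strategy recovery can be exercised end to end
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
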