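Package: ccckit
Title: Attention Network Effects and Cognitive Control Capacity in ADHD Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for cognitive control studies of
    children with ADHD, subthreshold ADHD, and typically developing controls.
    Generates synthetic cohorts with SNAP-IV/ASQ informant reports and applies
    two-informant diagnostic rules; builds and simulates trial schedules for the
    Attention Network Test - Interaction (ANT-I) and the backward-masked
    majority function task (MFT-M); scores alerting, orienting, and conflict
    network effects from cleaned reaction times; quantifies per-condition
    information content under the grouping-search strategy and estimates each
    subject's cognitive control capacity (bits per second) by maximum
    likelihood; flags deficits against typically-developing decile norms; and
    performs covariate-adjusted ANOVA, partial correlations, contingency tests,
    and repeated cross-validated linear SVM (cross-)classification with a
    shuffled-label baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    car,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
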