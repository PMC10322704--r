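Package: pupilcoding
Title: Pupillometry and Encoding-Model Analysis of Hypothalamic Arousal Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline linking hypothalamic orexin (hypocretin) cell
    activity to pupil-indexed arousal in head-fixed mice. Converts landmark
    tracking output into a pupil radius time series by confidence-gated
    algebraic circle fitting, produces neuropil-corrected and z-scored
    calcium dF/F traces and convex-hull-detrended photometry traces, fits a
    per-cell linear encoding model with leave-one-predictor-out variance
    partitioning across pupil, locomotion and reward predictors, computes
    lagged cross-correlation and multitaper coherence between neural
    activity and pupil size, and matches equivalent locomotion bouts across
    groups with k-means clustering for bout-aligned pupil comparisons. A
    synthetic-session generator with analytic ground truth supports
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    withr,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
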