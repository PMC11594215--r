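Package: greenwalk
Title: Continuous Heart Rate Variability and Cortisol Analysis for Crossover Nature-Walk Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing within-subject crossover walking studies that
    pair continuous heart rate variability (HRV) with salivary cortisol and
    mood-scale measurements. Provides readers and artifact filters for
    inter-beat-interval (RR/NN) recordings, time-domain HRV metrics (RMSSD,
    SDNN, AVNN) over non-overlapping short windows, smoothing-spline
    resampling of walk trajectories to a fixed number of comparable points,
    sign-based stratification of subjects by their green-minus-urban HRV
    response, paired tests and group summaries, cortisol percent-change and
    walk-order analyses, covariate-adjusted partial correlations between HRV
    and mood scores, through-origin weighted least-squares calibration for
    LC-MS cortisol quantitation, and a synthetic cohort generator with known
    ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
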