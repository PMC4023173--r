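Package: splitmeta
Title: Meta-Epidemiological Comparison of Split-Mouth and Parallel-Arm Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step meta-epidemiological analysis contrasting intervention
    effect estimates between split-mouth (within-subject) and parallel-arm
    randomized trials. Provides per-trial effect measures that respect paired
    data (marginal odds ratios for paired binary tables, standardized mean
    differences accounting for within-patient correlation), fixed-effect and
    REML random-effects inverse-variance pooling with heterogeneity statistics
    and prediction intervals, per-meta-analysis design contrasts (ratios of
    odds ratios and differences in standardized mean differences), pooling of
    contrasts across meta-analyses, a synthetic-data generator with the
    matching random-effects structure, and CSV/JSON input-output around the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
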