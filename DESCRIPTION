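Package: statescape
Title: Physiological State-Space Mapping of Transcriptomes and
    Early-Warning Resilience Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps bulk transcriptomes into a two-dimensional physiological
    state space (diurnal cycle x growth phase) from marker "state
    descriptor" transcripts selected by fold-change, significance and
    separation criteria on log10 FPKM, using piecewise per-transcript
    position scores. Quantifies loss of relational resilience ahead of
    population collapse with replicate similarity (Spearman), state-space
    dispersion (Euclidean distance, Mann-Whitney U), and coefficient of
    variation of photosynthetic efficiency Fv/Fm (Wilcoxon signed-rank).
    Includes logistic-with-lag growth-curve fitting, a fully labeled
    synthetic-study generator for end-to-end validation, and a
    reproducible pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
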