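Package: beccr
Title: Boolean Equivalent Correlated Clusters for Universal Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines large log2-scale expression compendia for universal
    co-expression biomarkers with the BECC (Boolean Equivalent Correlated
    Clusters) procedure. Fits rising one-step functions to per-probe
    expression (StepMiner), converts values to ternary Boolean calls with a
    noise margin, tests probe pairs for the six Boolean implication
    relations via sparse-quadrant BooleanNet statistics, expands a seed
    probeset through three rounds of Boolean equivalence, ranks candidates
    by a rank-weighted correlation/slope score, thresholds the scores with
    the same step fit, and calibrates the result against an empirical
    random-pair null. Includes the validation statistics used to vet
    candidate markers (high-high co-expression fraction, variance F-tests,
    correlation ranking) and a synthetic compendium generator with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
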