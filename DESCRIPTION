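Package: msnacor
Title: Cortical and Haemodynamic Correlates of Stimulus-Induced Sympathetic Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking muscle sympathetic nerve activity (MSNA)
    response profiles to beat-by-beat blood pressure, cortical oscillatory
    responses and cortical thickness. Implements the stimulus-locked MSNA
    inhibition statistic with Inhibitor classification, beat-aligned blood
    pressure group comparisons, LCMV beamformer source reconstruction with
    region-of-interest vertex selection, fixed-cycle Hanning-taper
    time-frequency decomposition, cluster-based permutation correlation
    statistics, and Spearman thickness correlations, together with a
    synthetic-data generator that emulates R-wave-locked stimulation
    experiments end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    readr,
    jsonlite,
    optparse
Config/testthat/edition: 3
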