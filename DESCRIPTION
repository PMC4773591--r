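Package: srtlearn
Title: Analysis of Online and Offline Learning in Serial Reaction Time Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing serial reaction time
    (SRT) experiments with fixed and first-order Markov (probabilistic) stimulus
    sequences. Provides constrained sequence generators (balanced blocks, no
    immediate repeats, per-stimulus quotas), an ex-Gaussian trial-level reaction
    time simulator with known online and offline learning parameters, standard
    deviation based outlier trimming, the online/offline/corrected-offline
    learning decomposition with probability-stratified variants, recall and
    recognition posttest scoring with analytic chance levels, and group-level
    inference: repeated-measures mixed models with AIC-selected residual
    covariance structures, factorial ANOVA, the Scheirer-Ray-Hare rank test,
    Tukey-Kramer post hoc comparisons and tests against chance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    nlme,
    car,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
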