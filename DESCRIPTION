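Package: saccfield
Title: Dynamic Neural Field Simulation of Saccadic Action Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates saccadic action selection in the intermediate layers of
    the superior colliculus with a one-dimensional, laterally-inhibitory dynamic
    neural field driven by eight neurophysiologically inspired component inputs
    (sensory, automated, voluntary and inhibitory). Runs a fully deterministic
    factorial experiment over pro- and anti-saccade trials (118,098 trials),
    classifies the resulting saccades into express and regular latency correct
    responses and direction errors, and provides the behavioural statistics
    used to study them: reaction-time histograms and summary tables,
    attribute-effect analyses (median shifts, Cohen's d, Kruskal-Wallis,
    chi-square selection tests), the anti-saccade difference curve with its
    voluntary override time, and post-hoc manipulations (input ablation,
    intentional-state trial filtering, and voluntary-to-automated inhibitory
    crosstalk).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    jsonlite,
    yaml,
    readr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
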