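Package: prlsim
Title: Simulation and Analysis of Probabilistic Reversal Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing rodent probabilistic reversal
    learning (PRL) experiments. Provides a deterministic-contract state machine
    for the 200-trial two-lever PRL session (80/20 reward contingencies,
    reversal after 8 consecutive correct presses), stochastic win-stay/
    lose-shift agents including a drowsy-perseverative phenotype with bout-
    structured omissions, trial-by-trial feedback classification and the six
    per-session readouts (probabilistic and actual lose-shift ratios, win-stay
    ratio, reversals, median press latency, omissions), a Latin-square
    crossover cohort generator, and the matching statistical battery
    (repeated-measures ANOVA with Sidak-corrected pairwise comparisons,
    Mauchly and Lilliefors checks, Friedman test with Dunn post hocs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
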