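Package: twinpgg
Title: Twin-Study Analysis of Public Goods Game Strategies and Simulated Payoffs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for behaviour-genetic analysis of public goods game
    strategy-method data from twin samples. Provides validated tabular
    containers for unconditional and conditional contribution schedules,
    composite decision scores and per-level summaries with trend
    regressions, within-pair intraclass correlations, a Bayesian ACE
    (additive genetic / shared environment / non-shared environment)
    variance-decomposition model fitted by Markov chain Monte Carlo with
    Gelman-Rubin convergence diagnostics and informative-prior chaining,
    Monte Carlo simulation of one-shot and iterated four-player public
    goods games from registered strategy schedules (with an exhaustive
    enumeration oracle), rank-based score-payoff association curves, and
    a synthetic twin-population generator with known latent ACE structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
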