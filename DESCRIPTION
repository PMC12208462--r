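Package: seqswap
Title: Serial Sequence Learning and Context-Cued Object Reordering Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serial object-sequence learning tasks in which
    a context cue instructs subjects to reorder non-adjacent items of a learned
    five-object sequence. Provides a generative task simulator with
    value-learning agents and a configurable strategy mixture (positional
    re-indexing versus serial chaining), learning-curve and error-taxonomy
    metrics, conditional transition-probability and swap-index statistics,
    Bayesian estimation of choice probabilities via a Metropolis-Hastings
    sampler on the probability simplex with Gelman-Rubin convergence
    diagnostics and strategy classification, and session-level analyses
    relating sequence memory, task experience and working memory (delayed
    match-to-sample accuracy) to reordering performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lmerTest,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
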