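Package: effortvns
Title: Effort Allocation Analysis for Auricular Vagus Nerve Stimulation
    Crossover Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of effort-allocation (button-press)
    experiments with transcutaneous auricular vagus nerve stimulation (taVNS)
    versus sham in a randomized crossover design. Generates synthetic
    two-session datasets driven by a cost-evidence accumulation model of
    work/rest bouts, extracts trial-level invigoration slopes and effort
    maintenance from press-rate series, fits linear mixed-effects models of
    stimulation effects with Jeffreys-Zellner-Siow Bayes factors, estimates
    the hierarchical Bayesian cost-evidence model by MCMC with Savage-Dickey
    Bayes factors for stimulation parameters, and tests taVNS-induced changes
    in the effort-utility slope with a permutation test on Huber robust
    regression coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    lme4,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
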