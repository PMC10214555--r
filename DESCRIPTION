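Package: vasnma
Title: Bayesian Network Meta-Analysis of Continuous VAS Pain Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evidence synthesis for arm-level aggregate trials reporting a
    continuous visual analog scale (VAS) pain outcome. Provides frequentist
    pairwise DerSimonian-Laird random-effects meta-analysis with
    heterogeneity statistics (Q, tau-squared, I-squared), a Bayesian
    random-effects network meta-analysis under the consistency model
    sampled by a Gibbs/slice MCMC scheme with over-dispersed chains,
    Brooks-Gelman-Rubin convergence diagnostics (PSRF), posterior
    treatment-rank probabilities and league tables, a synthetic
    trial-network simulator with known ground truth for validation, and an
    end-to-end analysis driver with reproducible manifests. Ships an
    8-study greater trochanteric pain syndrome (GTPS) trial network as a
    packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
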