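Package: ccscan
Title: Convergent Amino-Acid Substitutions at Conservative Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects parallel amino-acid substitutions shared by a set of
    foreground (trait-bearing) species against a background clade, using the
    convergence-at-conservative-sites (CCS) restriction to suppress noise from
    chance substitutions and ancestral-state misreconstruction. Provides a
    JTT + discrete-gamma amino-acid substitution model, Felsenstein-pruning
    likelihoods with maximum-likelihood branch-length and gamma-shape
    estimation, marginal empirical-Bayes ancestral reconstruction, a null
    sequence simulator with planted convergent substitutions for calibration,
    site-level convergence classification with random/false noise attribution,
    and downstream evidence filters for dN/dS curation, positive-selection
    screens, and differential-expression thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
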