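Package: divergome
Title: Growth of the Divergent Genome Under Speciation Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coalescent simulation and genome-scan toolkit for studying how
    the "divergent genome" (the set of F_ST outlier windows between sister
    species) grows with divergence time. Simulates two-population
    isolation-with-migration histories with recombination (SMC'
    approximation), epoch-limited gene flow and optional linked divergent
    selection; evolves finite-sites Jukes-Cantor sequences along the local
    genealogies; computes windowed Hudson F_ST, d_xy and fixed differences;
    calls outlier windows against pooled percentile thresholds (including a
    relaxed 95%+75% bridging rule); fits origin-constrained linear and
    exponential growth curves to divergent-genome size versus divergence
    time with AIC model comparison; and compares exponential growth
    coefficients across gene-flow scenarios with ANOVA, Tukey HSD and BCa
    bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    boot
Config/testthat/edition: 3
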