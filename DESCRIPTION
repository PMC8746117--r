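Package: gpdcnet
Title: Directed Functional Connectivity in Spiking Cortical Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a multi-area cortical network of conductance-based
    Hodgkin-Huxley spiking neurons wired by a weighted directed connectome
    (fraction-of-labeled-neurons matrices), synthesizes local field potential
    proxies from synaptic currents, and estimates directed functional
    connectivity with generalized partial directed coherence (GPDC) from
    multivariate autoregressive fits. Includes synthetic connectome and
    vector-autoregressive ground-truth generators, structure-function
    correlation analyses, activity-flow estimates, variability-versus-
    centrality summaries, and partial-observation (cluster) experiments with
    Welch tests under Holm-Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
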