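Package: gabrisk
Title: Functional Risk Analysis of GABA-A Receptor Gene Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the functional impact of missense variants
    in GABA-A receptor subunit genes (GABRs). Simulates macroscopic
    GABA-evoked currents from a five-state Markov kinetic scheme, fits
    multi-exponential activation and deactivation kinetics with F-test
    component selection, computes weighted time constants, current densities,
    zinc inhibition and the gating impairment ratio, fits Hill
    concentration-response curves and the variant/wild-type LogEC50 change
    ratio, manages rare-variant catalogs with domain and interface
    annotations, runs exact two-tailed Fisher association tests and
    many-to-one Dunnett comparisons against wild type, and scores
    mutation-induced structural perturbation from coordinate ensembles as
    per-element side-chain and secondary-structure RMS deviations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    multcomp,
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
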