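Package: stabsel
Title: Mean Fitness Under Stabilizing Selection in Finite Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form theory and individual-based simulation for the mean
    fitness of a finite population experiencing Gaussian stabilizing selection
    on an additive polygenic trait. Implements the stochastic house-of-cards
    approximation to the equilibrium genetic variance, the resulting
    expectation of population mean fitness over drift-driven fluctuations of
    the mean phenotype, and the condition under which a finite (often small)
    effective population size maximizes expected mean fitness. Every closed
    form is paired with an independent numerical oracle (adaptive quadrature,
    numeric maximization), and all predictions can be validated against a
    diploid Wright-Fisher forward simulator with infinite-sites mutation and
    free recombination. Includes a parameter-sweep pipeline with confidence
    intervals over replicate simulations, breakdown diagnostics, ggplot2
    visualisations and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
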