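Package: metadyn
Title: Well-Tempered Multi-Walker Metadynamics for Coarse-Grained
    Nucleic-Acid Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Enhanced-sampling toolkit for mapping deformation free-energy
    landscapes of coarse-grained nucleic-acid models. Implements
    well-tempered metadynamics with a gridded, history-dependent bias shared
    between multiple walkers; collective variables built from centre-of-mass
    distances, diagonal-distance pairs and signed bending angles; Langevin
    molecular dynamics with an Andersen-like thermostat and Metropolis Monte
    Carlo samplers; free-energy estimation from the converged bias and from
    histograms of biased production runs; and statistical reweighting with
    worm-like-chain entropic springs to predict constrained bending-angle
    distributions. Ships analytic benchmark landscapes and a kinkable
    bead-spring duplex analogue, plus readers and writers for oxDNA-format
    topology and configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
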