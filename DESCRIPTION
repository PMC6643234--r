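Package: batchflux
Title: Growth and Exchange-Flux Quantification from Batch Culture Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates specific growth rates and extracellular exchange
    (uptake and production) fluxes from batch-culture time courses of biomass
    and metabolite concentrations, accounting for first-order nonenzymatic
    degradation of unstable substrates such as dihydroxyacetone. Provides the
    analytical kinetic model and its ODE form, box-bounded nonlinear
    least-squares fitting with parametric-bootstrap precision estimates,
    first-order abiotic decay fitting with molar branch yields, carbon-molar
    (Cmmol) balancing of co-consumed substrates, synthetic data generation
    with known ground truth, and constraint-based (FBA/FVA) comparison of
    measured uptake fluxes against a genome-scale metabolic model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    minpack.lm,
    deSolve,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
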