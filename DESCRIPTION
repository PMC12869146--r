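Package: telespat
Title: Bayesian Spatial Modelling of Small-Area Telehealth Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Small-area analysis of telehealth uptake from claims-style visit
    records: synthetic lattice and claims generation, queen-contiguity
    adjacency graphs, cohort filtering with stage ledgers, use-rate and
    rurality-share summaries with a Cochran-Armitage trend test, covariate
    standardization and variance-inflation screening, a
    Metropolis-within-Gibbs sampler for the Besag-York-Mollie Poisson model
    with log-population offset, and posterior products (relative risks with
    credible intervals, DIC model comparison, exceedance-probability maps),
    validated against brute-force grid-integration posterior oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
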