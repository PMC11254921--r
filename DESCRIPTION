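Package: herbflux
Title: Insect Herbivory and Biogeochemical Element Fluxes in Broadleaved Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-balance accounting of the element fluxes mediated by
    background (non-outbreak) insect folivory in broadleaved forests.
    Converts litter-trap collections and binned visual leaf-damage scores
    into annual leaf litterfall, herbivory rate, foliar biomass production,
    gross consumed element fluxes, resorption efficiency with senescence
    mass-loss correction, and net insect-mediated element inputs for carbon,
    nitrogen, phosphorus and silicon. Includes zone summaries and comparison
    against atmospheric deposition and bedrock-weathering references,
    mixed-effects driver analysis with standardized coefficients and
    parametric-bootstrap confidence intervals, Kruskal-Wallis and Dunn
    post-hoc zone contrasts, and a synthetic plot-network generator with
    exposed ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
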