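Package: immunodem
Title: Immune Trade-Offs in an Age-Structured Life-History Framework
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how two immunological trade-offs -- the
    sensitivity-specificity trade-off of self/non-self discrimination and the
    trade-off between pathogen killing and immunopathology -- combine into
    age-specific survival, and how age-structured demography (Leslie-matrix
    growth rates, stable age structure, reproductive values and eigenvalue
    sensitivities) turns within-age survival optima into lifespan-level
    optimal immune strategies. Includes closed-form and numerical optima,
    bimodal survival landscapes, discrimination-response boundary maps, a
    scenario generator for sex-specific reproductive schedules and risks, and
    a stochastic two-generation simulation of immune memory and maternal
    antibody transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
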