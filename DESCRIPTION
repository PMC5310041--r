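Package: mitedef
Title: Resistance and Fecundity Tolerance to Water-Mite Parasitism in
    Polymorphic Damselflies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian analysis of host defence against ectoparasitic water
    mites in colour-polymorphic damselflies. Fits a zero-altered (hurdle)
    Poisson hierarchical model for parasite prevalence and infection
    intensity across phenotypes, a random-slope Poisson mixed model for
    the decline of female fecundity with mite load (tolerance), and
    derives morph-specific virulence by posterior resampling. Includes a
    calibrated synthetic survey generator for parameter-recovery studies,
    MCMC convergence diagnostics, and tidy summaries and plots of all
    fitted quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
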