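Package: tadevo
Title: Ancestral Reconstruction and Binding-Affinity Evolution of the
    p53TAD/MDM2 Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood ancestral sequence reconstruction of short
    protein regions on a time-calibrated species tree, with the tree surgery
    needed to represent the teleost whole-genome duplication (clade
    duplication at a stated age), JTT substitution models with discrete-gamma
    and invariant-site rate heterogeneity, AltAll alternative ancestral
    variants, and AICc/BIC substitution-model selection. Companion tools
    infer equilibrium dissociation constants from fluorescence-polarization
    saturation and displacement titrations (exact competitive-binding
    equilibria, IC50-to-KD conversion with free-concentration corrections)
    and from isothermal titration calorimetry, and provide summary analytics
    over an affinity table of motif versus full-length p53 transactivation
    domain interactions with MDM2 across ray-finned fishes. Synthetic-data
    generators for sequence evolution along a chronogram and for titration
    experiments make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
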