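Package: sexplast
Title: Sex-Specific Plasticity, Population Persistence, and Meta-Analysis of
    Thermal Reaction Norms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the consequences of sexually dimorphic
    phenotypic plasticity for population persistence under environmental
    change, and for meta-analysing sex-specific thermal plasticity. Provides
    closed-form steady-state growth rates and optimal dimorphism in reaction
    norms for a two-sex moving-optimum quantitative-genetic model (directional
    and cyclic regimes, female demographic dominance or co-dominance), a
    deterministic forward simulator that serves as a numerical oracle for the
    closed forms, paired effect-size computation (Hedges' d, lnCVR) with
    trait-class direction conventions and exclusion accounting, Grafen
    branch-length phylogenetic correlation matrices, a Gibbs-sampled
    phylogenetic multilevel meta-regression with known sampling covariances
    and sex-heteroscedastic residuals (heterogeneity I2 partitions, R2,
    folded-normal absolute effects, moderator and publication-bias refits),
    and a synthetic-data generator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
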