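Package: limbgen
Title: Bayesian Animal Models and Descriptive Genetics of Ordinal
    Limb-Conformation Defects
Version: 0.1.0
Authors@R:
    person("Menorca", "Quantitative Genetics", email = "limbgen@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative-genetic analysis of ordinal
    limb-conformation defects scored on a 0/1/2 scale in pedigreed horse
    populations.  Builds and validates pedigrees, computes inbreeding
    coefficients and the numerator relationship matrix with its sparse
    Henderson inverse, simulates repeatability-design phenotype records with
    known true parameters, fits multi-trait animal models with a permanent
    environmental effect by blocked Gibbs sampling, and summarises posterior
    draws into heritabilities, genetic correlations, highest posterior
    density intervals, Geweke Z and Monte Carlo standard error diagnostics.
    Also provides record-level prevalence tables, baseline-category
    multinomial-logit screening of non-genetic factors, and one-way gait-score
    comparisons with Tukey-Kramer post hoc letters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
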