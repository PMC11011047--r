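## Published reference values for the Menorca Purebred population, shipped
## as plain data for arithmetic cross-checks of the package's transforms.
## These are inputs (printed counts and posterior means), not outputs of
## this package.

#' Published prevalence counts for the Menorca Purebred population
#'
#' Record counts per 0/1/2 class for the fourteen defects, together with
#' the percentages as printed in the published prevalence table.  Used to
#' verify that [prevalence_table()] reproduces the printed percentages
#' from the raw counts.
#'
#' @return data.frame: trait, N, n0..n2, printed pct0..pct2 and pct12.
#' @export
reference_prevalence <- function() {
  utils::read.csv(system.file("extdata", "prme_prevalence_counts.csv", package = "limbgen"),
                  stringsAsFactors = FALSE)
}

#' Published variance components for the Menorca Purebred population
#'
#' Posterior means of the permanent environmental, additive genetic and
#' residual variances per defect, with the printed heritability (and its
#' s.d. and HPD bounds).  Used to verify the heritability transform
#' `u / (pe + u + e)` against the printed values.
#'
#' @return data.frame: trait, pe_mean, u_mean, e_mean, h2, h2_sd,
#'   h2_hpd_lower, h2_hpd_upper.
#' @export
reference_variance_components <- function() {
  utils::read.csv(system.file("extdata", "prme_variance_components.csv", package = "limbgen"),
                  stringsAsFactors = FALSE)
}
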