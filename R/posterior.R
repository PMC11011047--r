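## Posterior summaries and single-chain convergence diagnostics.

#' Heritability draws and summary for one trait
#'
#' Applies the repeatability-model heritability transform
#' `h2 = sigma_u / (sigma_u + sigma_pe + sigma_e)` draw by draw (never to
#' posterior means first) and summarises the resulting chain.
#'
#' @param fit a [run_gibbs()] result.
#' @param trait trait name or index.
#' @return list with `draws` and a `summary` row (mean, sd, median,
#'   HPD95 bounds).
#' @export
heritability_samples <- function(fit, trait) {
  stopifnot(inherits(fit, "gibbs_fit"))
  j <- if (is.character(trait)) match(trait, fit$meta$traits) else as.integer(trait)
  if (is.na(j) || j < 1 || j > length(fit$meta$traits)) stop("unknown trait: ", trait)
  if (fit$meta$nsave == 0L) stop("fit contains no saved draws")
  su <- fit$sigma_u[j, j, ]
  h2 <- su / (su + fit$sigma_pe[j, j, ] + fit$sigma_e[j, j, ])
  hpd <- hpd_interval(h2)
  list(draws = h2,
       summary = data.frame(trait = fit$meta$traits[j],
                            mean = mean(h2), sd = stats::sd(h2),
                            median = stats::median(h2),
                            hpd_lower = hpd[1], hpd_upper = hpd[2]))
}

#' Genetic-correlation draws and summary for a trait pair
#'
#' `r_g = sigma_u(i,j) / sqrt(sigma_u(i,i) sigma_u(j,j))`, applied draw by
#' draw.  The significance flag marks a 95% HPD interval that excludes
#' zero.
#'
#' @param fit a [run_gibbs()] result covering both traits.
#' @param trait_i,trait_j trait names or indices.
#' @return list with `draws` and a `summary` row (mean, sd, HPD95,
#'   significance flag).
#' @export
genetic_correlation_samples <- function(fit, trait_i, trait_j) {
  stopifnot(inherits(fit, "gibbs_fit"))
  tr <- fit$meta$traits
  i <- if (is.character(trait_i)) match(trait_i, tr) else as.integer(trait_i)
  j <- if (is.character(trait_j)) match(trait_j, tr) else as.integer(trait_j)
  if (anyNA(c(i, j)) || i == j) stop("trait pair not covered by this run")
  rg <- fit$sigma_u[i, j, ] / sqrt(fit$sigma_u[i, i, ] * fit$sigma_u[j, j, ])
  hpd <- hpd_interval(rg)
  list(draws = rg,
       summary = data.frame(trait_i = tr[i], trait_j = tr[j],
                            mean = mean(rg), sd = stats::sd(rg),
                            hpd_lower = hpd[1], hpd_upper = hpd[2],
                            significant = hpd[1] > 0 | hpd[2] < 0))
}

## Spectral density of a chain at frequency zero, via an AR fit
## (autoregressive analogue of a lag-window estimate).
spectrum0 <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(30L, floor(length(x) / 20))),
    error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence Z score
#'
#' Compares the mean of the first `first_frac` of the chain with the mean
#' of the last `last_frac`, standardised by spectral-density-at-zero
#' variance estimates of each window.  |Z| > 2 flags disagreement between
#' the early and late parts of the chain.
#'
#' @param chain numeric draw sequence (length >= 100).
#' @param first_frac,last_frac window fractions (defaults 0.1 and 0.5).
#' @return the Z statistic (0, with a warning, for a constant chain).
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (n < 100) stop("chain too short for the Geweke diagnostic (need >= 100)")
  stopifnot(first_frac > 0, last_frac > 0, first_frac + last_frac <= 1)
  if (stats::var(chain) == 0) {
    warning("constant chain; Geweke Z defined as 0")
    return(0)
  }
  a <- chain[seq_len(floor(first_frac * n))]
  b <- chain[seq.int(n - floor(last_frac * n) + 1L, n)]
  va <- spectrum0(a) / length(a)
  vb <- spectrum0(b) / length(b)
  if (va + vb == 0) {
    warning("degenerate windows; Geweke Z defined as 0")
    return(0)
  }
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Monte Carlo standard error by batch means
#'
#' Splits the chain into `floor(sqrt(n))` consecutive batches and uses the
#' standard deviation of the batch means.
#'
#' @param chain numeric draw sequence (length >= 100).
#' @return the Monte Carlo standard error of the chain mean.
#' @export
mc_standard_error <- function(chain) {
  n <- length(chain)
  if (n < 100) stop("chain too short for a batch-means MCse (need >= 100)")
  nb <- floor(sqrt(n))
  bs <- n %/% nb
  m <- colMeans(matrix(chain[seq_len(nb * bs)], nrow = bs))
  stats::sd(m) / sqrt(nb)
}

#' Highest posterior density interval
#'
#' Shortest interval containing the requested posterior mass, found by a
#' sliding window over the sorted draws.
#'
#' @param chain numeric draw sequence.
#' @param mass interval mass in (0, 1).
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(chain, mass = 0.95) {
  if (!is_number(mass) || mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(chain)
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(x[i], x[i + k])
}

#' Summarise a Gibbs run into a genetic-parameter report
#'
#' Per-trait posterior summaries (mean, median, HPD95) of the three
#' variance components and of heritability, pairwise genetic correlations
#' with significance flags, and convergence diagnostics (Geweke Z, batch
#' means MCse) for every monitored scalar; scalars with |Z| > 2 or MCse
#' above the threshold are flagged.
#'
#' @param fit a [run_gibbs()] result.
#' @param mcse_threshold flag threshold for the Monte Carlo standard error
#'   of heritability/correlation chains.
#' @param digits rounding for the printed report (summaries themselves are
#'   kept at full precision).
#' @return list of class `"genetic_report"` with data.frames
#'   `heritability`, `components`, `correlations`, `diagnostics`.
#' @export
summarize_run <- function(fit, mcse_threshold = 0.001, digits = 2) {
  stopifnot(inherits(fit, "gibbs_fit"))
  tr <- fit$meta$traits
  t_ <- length(tr)

  comp_rows <- list(); her_rows <- list(); diag_rows <- list()
  for (j in seq_len(t_)) {
    for (cmp in c("sigma_pe", "sigma_u", "sigma_e")) {
      d <- fit[[cmp]][j, j, ]
      hpd <- hpd_interval(d)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        trait = tr[j], component = sub("sigma_", "", cmp),
        mean = mean(d), median = stats::median(d),
        hpd_lower = hpd[1], hpd_upper = hpd[2])
    }
    h <- heritability_samples(fit, j)
    her_rows[[j]] <- h$summary
    z <- geweke_z(h$draws)
    mcse <- mc_standard_error(h$draws)
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      scalar = paste0("h2_", tr[j]), geweke_z = z, mcse = mcse,
      flagged = abs(z) > 2 | mcse > mcse_threshold)
  }

  cor_rows <- list()
  if (t_ > 1) {
    for (i in seq_len(t_ - 1)) for (j in (i + 1):t_) {
      g <- genetic_correlation_samples(fit, i, j)
      cor_rows[[length(cor_rows) + 1L]] <- g$summary
      z <- geweke_z(g$draws)
      mcse <- mc_standard_error(g$draws)
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        scalar = paste0("rg_", tr[i], "_", tr[j]), geweke_z = z, mcse = mcse,
        flagged = abs(z) > 2 | mcse > mcse_threshold)
    }
  }

  rep_ <- list(
    heritability = do.call(rbind, her_rows),
    components = do.call(rbind, comp_rows),
    correlations = if (length(cor_rows)) do.call(rbind, cor_rows) else NULL,
    diagnostics = do.call(rbind, diag_rows),
    digits = digits,
    meta = fit$meta
  )
  class(rep_) <- "genetic_report"
  rep_
}

#' @export
print.genetic_report <- function(x, ...) {
  d <- x$digits
  cat("Genetic parameter report (", x$meta$nsave, " draws)\n", sep = "")
  h <- x$heritability
  h[, -1] <- round(h[, -1], d)
  print(h, row.names = FALSE)
  if (!is.null(x$correlations)) {
    cat("\nGenetic correlations:\n")
    cr <- x$correlations
    cr[, 3:6] <- round(cr[, 3:6], d)
    print(cr, row.names = FALSE)
  }
  if (any(x$diagnostics$flagged)) {
    cat("\nConvergence flags:\n")
    print(x$diagnostics[x$diagnostics$flagged, ], row.names = FALSE)
  } else {
    cat("\nAll monitored scalars pass |Geweke Z| <= 2 and the MCse threshold.\n")
  }
  invisible(x)
}

#' Point heritability from posterior-mean components
#'
#' The transform `u / (pe + u + e)` applied to already-averaged variance
#' components, as used when only published posterior means are available.
#' Note this differs from the draw-wise transform used on chains.
#'
#' @param pe,u,e posterior-mean variance components.
#' @param digits rounding (half away from zero), matching printed tables.
#' @return rounded point heritability.
#' @export
h2_from_means <- function(pe, u, e, digits = 2) {
  round_half_up(u / (pe + u + e), digits)
}
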