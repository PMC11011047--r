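# Independent oracles and fixture builders.  Everything here is coded
# naively (dense double loops, scalar Gibbs) on purpose, so that it stays
# independent of the package's optimised implementations.

# Brute-force tabular relationship matrix from parent row indices
# (0 = unknown).  Row-ordered pedigree assumed.
oracle_tabular_A <- function(sire_row, dam_row) {
  n <- length(sire_row)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire_row[i]; d <- dam_row[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        a <- 0
        if (s > 0) a <- a + 0.5 * A[j, s]
        if (d > 0) a <- a + 0.5 * A[j, d]
        A[i, j] <- A[j, i] <- a
      }
    }
    A[i, i] <- if (s > 0 && d > 0) 1 + 0.5 * A[s, d] else 1
  }
  A
}

# Random pedigree: nf founders then random matings among earlier animals,
# returned with shuffled rows so sorting is exercised.
random_raw_pedigree <- function(n, nf, seed, shuffle = TRUE) {
  set.seed(seed)
  id <- sprintf("P%04d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    pr <- sample(seq_len(i - 1), 2)
    sire[i] <- id[pr[1]]; dam[i] <- id[pr[2]]
  }
  yr <- 1960L + (seq_len(n) %/% 10L)
  df <- ped_table(id, sire, dam, yr, sample(c("male", "female"), n, TRUE))
  if (shuffle) df <- df[sample.int(n), ]
  df
}

# Scalar one-way Gibbs sampler for y_ij = mu + a_i + p_i + e_ij with iid
# animal effects a (the "genetic" effect under A = I) and p (permanent
# environment), flat priors on mu and all variances.  Returns h2 draws
# sigma_a^2 / (sigma_a^2 + sigma_p^2 + sigma_e^2).  Written single-site.
oracle_oneway_gibbs <- function(y, group, n_iter, burn_in, thin, seed,
                                floor = 1e-8) {
  set.seed(seed)
  g <- as.integer(factor(group))
  q <- max(g)
  n <- length(y)
  ni <- tabulate(g, q)
  mu <- mean(y)
  a <- p <- numeric(q)
  s2a <- s2p <- s2e <- stats::var(y) / 3
  out <- numeric((n_iter - burn_in) %/% thin)
  k <- 0L
  for (it in seq_len(n_iter)) {
    r <- y - mu - p[g]
    rbar <- tapply(r, g, sum) / ni
    va <- 1 / (ni / s2e + 1 / s2a)
    a <- rnorm(q, va * ni * rbar / s2e, sqrt(va))
    r <- y - mu - a[g]
    rbar <- tapply(r, g, sum) / ni
    vp <- 1 / (ni / s2e + 1 / s2p)
    p <- rnorm(q, vp * ni * rbar / s2e, sqrt(vp))
    r <- y - a[g] - p[g]
    mu <- rnorm(1, mean(r), sqrt(s2e / n))
    e <- r - mu
    s2a <- max(floor, sum(a^2) / rchisq(1, q - 2))
    s2p <- max(floor, sum(p^2) / rchisq(1, q - 2))
    s2e <- max(floor, sum(e^2) / rchisq(1, n - 2))
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      k <- k + 1L
      out[k] <- s2a / (s2a + s2p + s2e)
    }
  }
  out
}

# AR(1) chain with unit innovation-free marginal variance
ar1_chain <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n, sd = sqrt(1 - phi^2)))
}

# Records data.frame with constant factor levels, for tiny fixtures
flat_records <- function(animal, y, trait = "t1") {
  lev <- limbgen:::default_factor_levels()
  df <- data.frame(
    animal = animal,
    gender = lev$gender[1], birth_period = lev$birth_period[1],
    stud_criteria = lev$stud_criteria[1], age_group = lev$age_group[1],
    appraiser = lev$appraiser[1],
    stringsAsFactors = FALSE
  )
  y <- as.matrix(y)
  colnames(y) <- if (ncol(y) == 1) trait else paste0(trait, seq_len(ncol(y)))
  cbind(df, y)
}

# Study-shaped single-trait generator config used by the recovery checks:
# 500 evaluated animals, ~1100 records, pedigree depth 3, latent variance
# 1 split as h2 = 0.25, pe share 0.20.
recovery_config <- function(seed, sigma_u = 0.25, sigma_pe = 0.20, sigma_e = 0.55,
                            traits = "t1") {
  t_ <- length(traits)
  as_m <- function(x) if (is.matrix(x) || t_ == 1) x else diag(x, t_)
  sim_config(
    n_founders = 220, n_generations = 3, n_per_generation = 266,
    n_evaluated = 500, mean_records = 2.2,
    traits = traits,
    sigma_u = as_m(sigma_u), sigma_pe = as_m(sigma_pe), sigma_e = as_m(sigma_e),
    seed = seed
  )
}
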