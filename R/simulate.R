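## Synthetic repeatability-design data with known true parameters.
##
## The generator emulates the study design the package targets: a pedigree
## of roughly a thousand animals over a handful of non-overlapping
## generations, ~500 evaluated animals with on average 2.2 repeated records
## each, five cross-classified fixed factors (gender 2, birth period 3,
## stud selection criterion 4, evaluation-age group 2, appraiser 3), latent
## Gaussian trait values built from the animal-model decomposition
## y = Xb + u + pe + e, and an optional 0/1/2 discretisation.

#' Simulation configuration
#'
#' Returns a validated configuration list.  Defaults describe the
#' study-shaped world: 217 founders plus 4 generations of 200 offspring
#' (1017 animals), 500 evaluated animals with mean 2.2 records, a single
#' latent trait with variance partitioned as additive 0.25, permanent
#' environment 0.20, residual 0.55 (phenotypic variance 1), and modest
#' fixed-factor effects on the latent scale.
#'
#' @param n_founders,n_generations,n_per_generation pedigree shape.
#' @param n_evaluated number of (most recent) animals carrying records.
#' @param mean_records expected records per evaluated animal (>= 1; the
#'   count is 1 + Poisson(mean_records - 1)).
#' @param traits character vector of trait names.
#' @param sigma_u,sigma_pe,sigma_e genetic, permanent-environmental and
#'   residual covariance matrices (scalars accepted for one trait).
#' @param fixed_effects named list (gender, birth_period, stud_criteria,
#'   age_group, appraiser) of per-level effect vectors added to every
#'   trait's latent value; first level is the reference.
#' @param retention per-trait probability that a record's score is kept
#'   (trait-wise missingness).
#' @param thresholds optional named list of strictly increasing cutpoint
#'   pairs for 0/1/2 discretisation.
#' @param walk_mean,walk_sd,trot_mean,trot_sd gait-score distribution.
#' @param seed integer seed used by [sim_dataset()].
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_founders = 217, n_generations = 4, n_per_generation = 200,
                       n_evaluated = 500, mean_records = 2.2,
                       traits = "t1",
                       sigma_u = 0.25, sigma_pe = 0.20, sigma_e = 0.55,
                       fixed_effects = list(
                         gender = c(0, 0.2),
                         birth_period = c(0, -0.15, -0.3),
                         stud_criteria = c(0, -0.2, 0.1, 0.3),
                         age_group = c(0, 0.25),
                         appraiser = c(0, 0.3, -0.2)
                       ),
                       retention = 1,
                       thresholds = NULL,
                       walk_mean = 5.9, walk_sd = 1.52,
                       trot_mean = 5.6, trot_sd = 1.77,
                       seed = 1L) {
  t_ <- length(traits)
  as_cov <- function(x, nm) {
    if (is.null(dim(x))) x <- diag(x, t_, t_)
    x <- as.matrix(x)
    if (!isTRUE(all.equal(dim(x), c(t_, t_))))
      stop(nm, " must be a ", t_, "x", t_, " covariance matrix")
    if (max(abs(x - t(x))) > 1e-10) stop(nm, " must be symmetric")
    if (any(x != 0) && min(eigen(x, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop(nm, " must be positive definite (or all-zero)")
    dimnames(x) <- list(traits, traits)
    x
  }
  if (n_founders < 2) stop("n_founders must be at least 2")
  retention <- rep_len(retention, t_)
  if (any(retention <= 0 | retention > 1)) stop("retention probabilities must lie in (0, 1]")
  if (!is.null(thresholds)) {
    stopifnot(is.list(thresholds), all(names(thresholds) %in% traits))
    for (th in thresholds)
      if (length(th) != 2 || th[1] > th[2]) stop("thresholds must be non-decreasing pairs")
  }
  cfg <- list(
    n_founders = n_founders, n_generations = n_generations,
    n_per_generation = n_per_generation, n_evaluated = n_evaluated,
    mean_records = mean_records, traits = traits,
    sigma_u = as_cov(sigma_u, "sigma_u"),
    sigma_pe = as_cov(sigma_pe, "sigma_pe"),
    sigma_e = as_cov(sigma_e, "sigma_e"),
    fixed_effects = fixed_effects,
    retention = stats::setNames(retention, traits),
    thresholds = thresholds,
    walk_mean = walk_mean, walk_sd = walk_sd,
    trot_mean = trot_mean, trot_sd = trot_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a non-overlapping-generation pedigree
#'
#' Founders get alternating sexes; each later generation is produced by
#' random mating (sire drawn from the previous generation's males, dam from
#' its females).  Birth years are drawn uniformly within per-cohort windows
#' partitioning 1961-2020, so derived birth periods overlap cohorts the way
#' a real studbook does and all three periods occur among recent animals.
#'
#' @param cfg a [sim_config()].
#' @return a sorted pedigree (`"ped_table"`) with a `generation` attribute
#'   (integer vector in pedigree order, founders 0).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founders < 2) stop("n_founders must be at least 2")
  n_total <- cfg$n_founders + cfg$n_generations * cfg$n_per_generation
  id <- sprintf("A%05d", seq_len(n_total))
  sex <- character(n_total)
  sire <- dam <- rep(NA_character_, n_total)
  gen <- integer(n_total)
  sex[seq_len(cfg$n_founders)] <- rep_len(c("male", "female"), cfg$n_founders)
  year <- integer(n_total)
  ## cohort c (founders = 0) born uniformly within its window of 1961-2020
  n_cohorts <- cfg$n_generations + 1L
  year_of <- function(cohort, k) {
    lo <- 1961 + (cohort) * 59 / n_cohorts
    hi <- 1961 + (cohort + 1) * 59 / n_cohorts
    as.integer(floor(stats::runif(k, lo, hi)))
  }
  year[seq_len(cfg$n_founders)] <- year_of(0L, cfg$n_founders)
  prev <- seq_len(cfg$n_founders)
  nxt <- cfg$n_founders
  if (cfg$n_generations > 0) {
    for (g in seq_len(cfg$n_generations)) {
      males <- prev[sex[prev] == "male"]
      females <- prev[sex[prev] == "female"]
      if (!length(males) || !length(females))
        stop("generation ", g - 1, " lacks parents of both sexes")
      idx <- nxt + seq_len(cfg$n_per_generation)
      sire[idx] <- id[sample(males, cfg$n_per_generation, replace = TRUE)]
      dam[idx] <- id[sample(females, cfg$n_per_generation, replace = TRUE)]
      sex[idx] <- sample(c("male", "female"), cfg$n_per_generation, replace = TRUE)
      year[idx] <- year_of(g, cfg$n_per_generation)
      gen[idx] <- g
      prev <- idx
      nxt <- nxt + cfg$n_per_generation
    }
  }
  ped <- validate_and_sort(ped_table(id, sire, dam, year, sex))
  attr(ped, "generation") <- gen[match(ped$animal, id)]
  ped
}

#' Simulate true breeding values along a pedigree
#'
#' Downward gametic recursion `u_i = 0.5 (u_s + u_d) + m_i` with Mendelian
#' sampling covariance `d_i * sigma_u`, `d_i = 0.5 - 0.25 (F_s + F_d)` for
#' both parents known, `0.75 - 0.25 F_p` for one, 1 for founders; founders
#' are drawn from N(0, sigma_u).  Marginally `vec(u) ~ N(0, A (x) sigma_u)`.
#'
#' @param ped a sorted pedigree.
#' @param sigma_u trait covariance matrix (PD, or all-zero for a null
#'   simulation).
#' @param seed optional integer seed.
#' @return matrix of breeding values, animals in pedigree order x traits.
#' @export
simulate_breeding_values <- function(ped, sigma_u, seed = NULL) {
  assert_sorted_ped(ped)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(sigma_u))) sigma_u <- as.matrix(sigma_u)
  t_ <- nrow(sigma_u)
  n <- nrow(ped)
  if (all(sigma_u == 0)) return(matrix(0, n, t_, dimnames = list(ped$animal, colnames(sigma_u))))
  if (min(eigen(sigma_u, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("sigma_u must be positive definite")
  f <- compute_inbreeding(ped)
  L <- chol(sigma_u)
  z <- matrix(stats::rnorm(n * t_), n, t_) %*% L
  u <- matrix(0, n, t_)
  s <- ped$sire_row
  d <- ped$dam_row
  for (i in seq_len(n)) {
    if (s[i] > 0L && d[i] > 0L) {
      di <- 0.5 - 0.25 * (f[s[i]] + f[d[i]])
      u[i, ] <- 0.5 * (u[s[i], ] + u[d[i], ]) + sqrt(di) * z[i, ]
    } else if (s[i] > 0L || d[i] > 0L) {
      p <- max(s[i], d[i])
      di <- 0.75 - 0.25 * f[p]
      u[i, ] <- 0.5 * u[p, ] + sqrt(di) * z[i, ]
    } else {
      u[i, ] <- z[i, ]
    }
  }
  dimnames(u) <- list(ped$animal, colnames(sigma_u))
  u
}

#' Simulate repeated phenotype records
#'
#' Evaluated animals (by default the `n_evaluated` most recent pedigree
#' rows) receive `1 + Poisson(mean_records - 1)` records each.  Gender,
#' birth period (derived from pedigree birth year) and stud criterion are
#' fixed per animal; appraiser and evaluation-age group vary per record.
#' Latent trait values are `fixed effects + u + pe + e`; per-trait
#' missingness is applied to the latent columns, guaranteeing at least one
#' retained trait per record.  Walk and trot scores are drawn around their
#' configured means.
#'
#' @param ped sorted pedigree.
#' @param u breeding-value matrix from [simulate_breeding_values()].
#' @param cfg a [sim_config()].
#' @param evaluated optional character vector of animal ids to evaluate.
#' @param seed optional integer seed.
#' @return data.frame of records (latent scores in `<trait>_latent`
#'   columns) with attribute `true_pe` (evaluated-animal matrix).
#' @export
simulate_records <- function(ped, u, cfg, evaluated = NULL, seed = NULL) {
  assert_sorted_ped(ped)
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  traits <- cfg$traits
  t_ <- length(traits)
  if (is.null(evaluated))
    evaluated <- utils::tail(ped$animal, cfg$n_evaluated)
  miss <- setdiff(evaluated, ped$animal)
  if (length(miss)) stop("evaluated animals absent from pedigree: ", paste(utils::head(miss, 3), collapse = ", "))
  n_ev <- length(evaluated)
  erow <- match(evaluated, ped$animal)

  nrec <- 1L + stats::rpois(n_ev, max(0, cfg$mean_records - 1))
  anim <- rep(evaluated, nrec)
  n <- length(anim)
  arow <- rep(erow, nrec)
  eidx <- rep(seq_len(n_ev), nrec)

  ## animal-level factors
  gender <- ped$sex[erow]
  gender[!(gender %in% c("male", "female"))] <- sample(c("male", "female"),
                                                       sum(!(gender %in% c("male", "female"))),
                                                       replace = TRUE)
  by <- ped$birth_year[erow]
  by[is.na(by)] <- 2005L
  birth_period <- cut(by, breaks = c(-Inf, 2000, 2010, Inf),
                      labels = c("<=2000", "2001-2010", ">2010"))
  birth_period <- as.character(birth_period)
  stud_criteria <- sample(c("functionality", "conformation", "routes", "breeding"),
                          n_ev, replace = TRUE, prob = c(0.30, 0.25, 0.25, 0.20))
  ## record-level factors
  age_group <- sample(c("young", "adult"), n, replace = TRUE, prob = c(0.3, 0.7))
  appraiser <- sample(c("1", "2", "3"), n, replace = TRUE, prob = c(0.35, 0.40, 0.25))

  fe <- cfg$fixed_effects
  lev <- default_factor_levels()
  fx <- fe$gender[match(gender[eidx], lev$gender)] +
    fe$birth_period[match(birth_period[eidx], lev$birth_period)] +
    fe$stud_criteria[match(stud_criteria[eidx], lev$stud_criteria)] +
    fe$age_group[match(age_group, lev$age_group)] +
    fe$appraiser[match(appraiser, lev$appraiser)]

  pe <- if (all(cfg$sigma_pe == 0)) matrix(0, n_ev, t_) else rmvn0(n_ev, cfg$sigma_pe)
  e <- if (all(cfg$sigma_e == 0)) matrix(0, n, t_) else rmvn0(n, cfg$sigma_e)
  y <- fx + u[arow, , drop = FALSE] + pe[eidx, , drop = FALSE] + e

  ## per-trait missingness, keeping at least one trait per record
  keep <- matrix(stats::runif(n * t_) <= rep(cfg$retention, each = n), n, t_)
  none <- which(rowSums(keep) == 0L)
  if (length(none)) keep[cbind(none, sample.int(t_, length(none), replace = TRUE))] <- TRUE
  y[!keep] <- NA_real_

  rec <- data.frame(
    record_id = seq_len(n),
    animal = anim,
    gender = gender[eidx],
    birth_period = birth_period[eidx],
    stud_criteria = stud_criteria[eidx],
    age_group = age_group,
    appraiser = appraiser,
    walk = pmin(7, pmax(1, round(stats::rnorm(n, cfg$walk_mean, cfg$walk_sd), 1))),
    trot = pmin(7, pmax(1, round(stats::rnorm(n, cfg$trot_mean, cfg$trot_sd), 1))),
    stringsAsFactors = FALSE
  )
  colnames(y) <- paste0(traits, "_latent")
  rec <- cbind(rec, as.data.frame(y))
  rownames(pe) <- evaluated
  colnames(pe) <- traits
  attr(rec, "true_pe") <- pe
  rec
}

#' Discretise latent scores to the 0/1/2 defect scale
#'
#' Class 0 below the first cutpoint, 1 between the two, 2 at or above the
#' second.  Adds one integer column per trait next to the latent columns.
#'
#' @param records record data.frame with `<trait>_latent` columns.
#' @param thresholds named list of strictly increasing cutpoint pairs, one
#'   per trait to discretise.
#' @return `records` with added `<trait>` class columns.
#' @export
discretize_to_classes <- function(records, thresholds) {
  stopifnot(is.list(thresholds))
  for (tr in names(thresholds)) {
    th <- thresholds[[tr]]
    if (length(th) != 2 || th[1] > th[2])
      stop("thresholds for ", tr, " must be two non-decreasing values")
    lat <- records[[paste0(tr, "_latent")]]
    if (is.null(lat)) stop("no latent column for trait ", tr)
    records[[tr]] <- ifelse(is.na(lat), NA_integer_,
                            ifelse(lat < th[1], 0L, ifelse(lat < th[2], 1L, 2L)))
  }
  records
}

#' Cutpoints matching target class frequencies
#'
#' Chooses thresholds as quantiles of the observed latent scores so that the
#' empirical 0/1/2 shares approximate the given percentages.
#'
#' @param latent numeric vector of latent scores.
#' @param shares length-3 vector of target percentages (sums to ~100).
#' @return numeric cutpoint pair.
#' @export
thresholds_from_shares <- function(latent, shares) {
  stopifnot(length(shares) == 3)
  p <- shares / sum(shares)
  stats::quantile(latent, probs = cumsum(p)[1:2], na.rm = TRUE, names = FALSE)
}

#' Shift gait scores by defect class
#'
#' Applies additive per-class shifts to the walk and/or trot columns, used
#' to inject a known gait signal for power checks.
#'
#' @param records record data.frame holding a `<trait>` class column.
#' @param trait trait whose class drives the shift.
#' @param walk_shift,trot_shift length-3 per-class additive shifts.
#' @return modified records.
#' @export
shift_gait_by_class <- function(records, trait, walk_shift = c(0, 0, 0), trot_shift = c(0, 0, 0)) {
  cl <- records[[trait]]
  ok <- !is.na(cl)
  records$walk[ok] <- records$walk[ok] + walk_shift[cl[ok] + 1L]
  records$trot[ok] <- records$trot[ok] + trot_shift[cl[ok] + 1L]
  records
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generator under the configuration seed: pedigree, breeding
#' values, permanent environmental values, repeated records and (when
#' thresholds are configured) 0/1/2 class columns.  Byte-identical across
#' runs for a fixed configuration.
#'
#' @param cfg a [sim_config()].
#' @return list of class `"sim_dataset"` with elements `pedigree`,
#'   `records`, `true_u`, `true_pe`, `config`.
#' @export
sim_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  u <- simulate_breeding_values(ped, cfg$sigma_u)
  rec <- simulate_records(ped, u, cfg)
  if (!is.null(cfg$thresholds)) rec <- discretize_to_classes(rec, cfg$thresholds)
  out <- list(pedigree = ped, records = rec,
              true_u = u, true_pe = attr(rec, "true_pe"), config = cfg)
  class(out) <- "sim_dataset"
  out
}

## Canonical factor levels shared by the generator, the design builder and
## the readers.  First level of each factor is the reference.
default_factor_levels <- function() {
  list(
    gender = c("male", "female"),
    birth_period = c("<=2000", "2001-2010", ">2010"),
    stud_criteria = c("functionality", "conformation", "routes", "breeding"),
    age_group = c("young", "adult"),
    appraiser = c("1", "2", "3")
  )
}
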