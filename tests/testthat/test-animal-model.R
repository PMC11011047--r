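test_that("design matrices use reference coding and align incidence", {
  ## all factors at their first level: X collapses to the intercept
  ped <- validate_and_sort(ped_table(c("a1", "a2")))
  rec <- flat_records(c("a1", "a2"), c(1.0, 2.0))
  spec <- model_spec("t1", n_iterations = 10, burn_in = 1)
  mme <- build_design_matrices(rec, ped, spec)
  expect_identical(colnames(mme$X), "(Intercept)")
  expect_identical(mme$p, 1L)

  ## study-shaped data: 1 + 1 + 2 + 3 + 1 + 2 = 10 columns
  ## (all three birth periods must be observed, hence 4 generations)
  dat <- sim_dataset(sim_config(n_founders = 60, n_generations = 4, n_per_generation = 50,
                                n_evaluated = 130, seed = 3))
  spec2 <- model_spec("t1_latent", n_iterations = 10, burn_in = 1)
  mme2 <- build_design_matrices(dat$records, dat$pedigree, spec2)
  expect_identical(ncol(mme2$X), 10L)
  expect_identical(qr(mme2$X)$rank, 10L)

  ## W column sum equals the animal's record count
  counts <- table(dat$records$animal)
  an <- names(counts)[counts == max(counts)][1]
  j <- match(an, mme2$pe_ids)
  expect_identical(sum(mme2$W[, j]), as.numeric(counts[an]))

  ## errors
  bad <- dat$records
  bad$gender[1] <- "stallion"
  expect_error(build_design_matrices(bad, dat$pedigree, spec2), "undeclared level")
  bad2 <- dat$records
  bad2$t1_latent <- NA_real_
  expect_error(build_design_matrices(bad2, dat$pedigree, spec2), "no observed scores")
  bad3 <- dat$records
  bad3$animal[1] <- "ghost"
  expect_error(build_design_matrices(bad3, dat$pedigree, spec2), "absent from pedigree")
})

test_that("records with all traits missing are dropped, others masked", {
  ped <- validate_and_sort(ped_table(c("a1", "a2", "a3")))
  rec <- flat_records(rep(c("a1", "a2", "a3"), 2), cbind(c(1, 2, NA, 4, 5, 6), c(1, NA, NA, 4, 5, 6)))
  spec <- model_spec(c("t11", "t12"), n_iterations = 10, burn_in = 1)
  expect_warning(mme <- build_design_matrices(rec, ped, spec), "dropped")
  expect_identical(mme$n, 5L)
  expect_identical(sum(!mme$obs), 1L)

  spec_cc <- model_spec(c("t11", "t12"), n_iterations = 10, burn_in = 1,
                        missing_handling = "complete_cases")
  expect_warning(mme_cc <- build_design_matrices(rec, ped, spec_cc), "dropped")
  expect_identical(mme_cc$n, 4L)
})

test_that("location draws collapse to OLS when random variances vanish", {
  set.seed(31)
  n <- 50
  ped <- validate_and_sort(ped_table(sprintf("a%02d", 1:25)))
  rec <- flat_records(rep(sprintf("a%02d", 1:25), 2), rnorm(n))
  rec$gender <- sample(c("male", "female"), n, TRUE)
  rec$appraiser <- sample(c("1", "2", "3"), n, TRUE)
  spec <- model_spec("t1", n_iterations = 10, burn_in = 1)
  mme <- build_design_matrices(rec, ped, spec)
  state <- list(y = mme$y, b = matrix(0, mme$p, 1), u = matrix(0, mme$q, 1),
                pe = matrix(0, mme$pa, 1),
                sigma_u = matrix(1e-9), sigma_pe = matrix(1e-9), sigma_e = matrix(1))
  ndr <- 2000
  bs <- matrix(NA_real_, ndr, mme$p)
  set.seed(32)
  for (r in seq_len(ndr)) {
    state <- sample_location_effects(state, mme)
    bs[r, ] <- state$b
  }
  ols <- qr.coef(qr(mme$X), mme$y[, 1])
  mc_se <- apply(bs, 2, stats::sd) / sqrt(ndr)
  expect_true(all(abs(colMeans(bs) - ols) < 3 * mc_se + 1e-6))
})

test_that("variance full conditionals match closed-form moments", {
  ## univariate residual: draws follow S / chisq(n - 2), mean S / (n - 4)
  n <- 100
  ped <- validate_and_sort(ped_table(sprintf("a%03d", 1:50)))
  set.seed(41)
  e <- rnorm(n)
  rec <- flat_records(rep(sprintf("a%03d", 1:50), 2), e)
  spec <- model_spec("t1", n_iterations = 10, burn_in = 1)
  mme <- build_design_matrices(rec, ped, spec)
  S <- sum(e^2)
  state0 <- list(y = mme$y, b = matrix(0, mme$p, 1), u = matrix(0, mme$q, 1),
                 pe = matrix(0, mme$pa, 1),
                 sigma_u = matrix(1), sigma_pe = matrix(1), sigma_e = matrix(1))
  draws <- numeric(20000)
  set.seed(42)
  for (r in seq_along(draws)) {
    st <- sample_variance_components(state0, mme)
    draws[r] <- st$sigma_e[1, 1]
  }
  expect_lt(abs(mean(draws) - S / (n - 4)) / (S / (n - 4)), 0.02)

  ## bivariate genetic component: posterior mean ~ u' A^-1 u / q
  q <- 400
  pedq <- validate_and_sort(ped_table(sprintf("b%03d", 1:q)))
  Su_true <- matrix(c(1, 0.5, 0.5, 2), 2)
  set.seed(43)
  U <- simulate_breeding_values(pedq, Su_true)
  recq <- flat_records(pedq$animal, matrix(0, q, 2))
  specq <- model_spec(c("t11", "t12"), n_iterations = 10, burn_in = 1)
  mmeq <- build_design_matrices(recq, pedq, specq)
  Sq <- crossprod(U)   # A = I for founders
  stateq <- list(y = mmeq$y, b = matrix(0, mmeq$p, 2), u = U,
                 pe = matrix(0, mmeq$pa, 2),
                 sigma_u = diag(2), sigma_pe = diag(2), sigma_e = diag(2))
  acc <- matrix(0, 2, 2)
  ndr <- 4000
  set.seed(44)
  for (r in seq_len(ndr)) {
    st <- sample_variance_components(stateq, mmeq)
    acc <- acc + st$sigma_u
  }
  expect_lt(max(abs(acc / ndr - Sq / q) / (Sq / q)), 0.05)

  ## degenerate zero-residual data: draws collapse to the floor, no error
  state0$y[] <- 0
  st0 <- sample_variance_components(state0, mme)
  expect_lt(st0$sigma_e[1, 1], 1e-4)
})

test_that("missing-trait imputation draws from the right conditional", {
  q <- 30
  ped <- validate_and_sort(ped_table(sprintf("c%02d", 1:q)))
  Se <- matrix(c(1, 0.9, 0.9, 1), 2)
  n <- 400
  an <- rep(sprintf("c%02d", 1:q), length.out = n)
  set.seed(50)
  y <- cbind(rnorm(n), c(rnorm(20), rep(NA_real_, n - 20)))
  rec <- flat_records(an, y)
  spec <- model_spec(c("t11", "t12"), n_iterations = 10, burn_in = 1)
  mme <- suppressWarnings(build_design_matrices(rec, ped, spec))
  state <- list(y = mme$y, b = matrix(0, mme$p, 2), u = matrix(0, mme$q, 2),
                pe = matrix(0, mme$pa, 2),
                sigma_u = diag(2), sigma_pe = diag(2), sigma_e = Se)
  state$y[is.na(state$y)] <- 0
  mis <- which(!mme$obs[, 2])
  set.seed(51)
  imp <- replicate(200, impute_missing_traits(state, mme)$y[mis, 2])
  ## observed entries untouched; imputed draws correlate ~0.9 with the
  ## observed-trait residuals
  out <- impute_missing_traits(state, mme)
  expect_identical(out$y[, 1], mme$y[, 1])
  expect_identical(out$y[mme$obs[, 2], 2], mme$y[mme$obs[, 2], 2])
  expect_lt(abs(mean(apply(imp, 2, function(v) cor(v, mme$y[mis, 1]))) - 0.9), 0.05)

  ## diagonal residual covariance: imputation mean equals the linear predictor
  state$sigma_e <- diag(2)
  state$b <- matrix(0.7, mme$p, 2)
  set.seed(52)
  imp2 <- replicate(400, impute_missing_traits(state, mme)$y[mis, 2])
  expect_lt(max(abs(rowMeans(imp2) - 0.7)), 0.25)
  expect_lt(abs(mean(imp2) - 0.7), 0.02)
})

test_that("run_gibbs is deterministic, counts draws exactly, handles degenerate data", {
  dat <- sim_dataset(sim_config(n_founders = 40, n_generations = 2, n_per_generation = 30,
                                n_evaluated = 50, seed = 61))
  spec <- model_spec("t1_latent", n_iterations = 730, burn_in = 100, thin = 7, seed = 3)
  f1 <- run_gibbs(dat$records, dat$pedigree, spec)
  f2 <- run_gibbs(dat$records, dat$pedigree, spec)
  expect_identical(f1$sigma_u, f2$sigma_u)
  expect_identical(f1$sigma_e, f2$sigma_e)
  expect_identical(dim(f1$sigma_u)[3], (730L - 100L) %/% 7L)

  ## constant response: location effects centre on zero, variances at floor
  recc <- dat$records
  recc$t1_latent <- 1
  fc <- run_gibbs(recc, dat$pedigree, model_spec("t1_latent", n_iterations = 300,
                                                 burn_in = 100, seed = 4))
  expect_lt(max(abs(fc$u_mean)), 0.05)
  expect_lt(max(abs(fc$pe_mean)), 0.05)
  expect_lt(mean(fc$sigma_u[1, 1, ]), 1e-3)
})

test_that("relabelling animals leaves posterior summaries unchanged", {
  dat <- sim_dataset(sim_config(n_founders = 60, n_generations = 2, n_per_generation = 45,
                                n_evaluated = 60, seed = 71))
  spec <- model_spec("t1_latent", n_iterations = 3000, burn_in = 500, seed = 5)
  f1 <- run_gibbs(dat$records, dat$pedigree, spec)

  ## consistent relabelling of pedigree and records
  map <- stats::setNames(sprintf("R%05d", sample(nrow(dat$pedigree))), dat$pedigree$animal)
  ped2 <- ped_table(unname(map[dat$pedigree$animal]),
                    ifelse(is.na(dat$pedigree$sire), NA, unname(map[dat$pedigree$sire])),
                    ifelse(is.na(dat$pedigree$dam), NA, unname(map[dat$pedigree$dam])),
                    dat$pedigree$birth_year, dat$pedigree$sex)
  rec2 <- dat$records
  rec2$animal <- unname(map[rec2$animal])
  f2 <- run_gibbs(rec2, validate_and_sort(ped2), spec)

  h1 <- heritability_samples(f1, 1)$summary
  h2 <- heritability_samples(f2, 1)$summary
  ## blocked joint draws with fill-reducing orderings are not
  ## permutation-equivariant draw by draw; distributions must agree
  expect_lt(abs(h1$mean - h2$mean), 0.05)
  expect_lt(abs(h1$sd - h2$sd), 0.02)
})

test_that("augmented missing-data runs stay proper and bounded", {
  cfg <- sim_config(traits = c("a", "b"),
                    sigma_u = matrix(c(0.25, 0.1, 0.1, 0.25), 2),
                    sigma_pe = diag(0.2, 2), sigma_e = diag(0.55, 2),
                    n_founders = 50, n_generations = 2, n_per_generation = 40,
                    n_evaluated = 60, retention = c(0.8, 0.7), seed = 81)
  dat <- sim_dataset(cfg)
  spec <- model_spec(c("a_latent", "b_latent"), n_iterations = 400, burn_in = 100, seed = 6)
  fit <- suppressWarnings(run_gibbs(dat$records, dat$pedigree, spec))
  h <- heritability_samples(fit, "a_latent")$draws
  expect_true(all(h >= 0 & h <= 1))
  expect_identical(length(h), 300L)
})
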