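## Blocked Gibbs sampler for the multi-trait repeatability animal model.
##
## One sweep is: impute missing trait scores from their Gaussian
## conditional -> draw all location effects (b, u, pe) jointly from the
## Gaussian full conditional of the mixed-model equations -> draw the three
## covariance matrices from their inverse-Wishart full conditionals under
## flat (bounded-uniform) priors.
##
## The location draw needs the Cholesky factor of
##   C = Sigma_e^-1 (x) T'T + Sigma_u^-1 (x) A^-1 + Sigma_pe^-1 (x) P
## (T = [X Z W], P = I or A^-1).  The sparsity pattern of C is constant
## across iterations, so the workspace precomputes, once, the mapping from
## each template's nonzeros into the slots of C, and reuses the symbolic
## Cholesky analysis; per iteration only the numeric factorisation is
## redone.

pad_square <- function(M, off, D) {
  g <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  Matrix::sparseMatrix(i = g@i + 1L + off, j = g@j + 1L + off, x = g@x, dims = c(D, D))
}

gen_triplets <- function(M) {
  g <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  list(i = g@i + 1L, j = g@j + 1L, x = g@x)
}

gibbs_workspace <- function(mme) {
  if (!is.null(mme$cache$ws)) return(mme$cache$ws)
  t_ <- length(mme$traits)
  p <- mme$p; q <- mme$q; pa <- mme$pa
  D <- p + q + pa
  Tm <- cbind(Matrix::Matrix(mme$X, sparse = TRUE), mme$Z, mme$W)
  TtT <- Matrix::forceSymmetric(Matrix::crossprod(Tm))
  Au <- pad_square(mme$Ainv, p, D)
  Ppe <- if (mme$spec$pe_covariance == "identity") {
    pad_square(Matrix::Diagonal(pa, 1), p + q, D)
  } else {
    pad_square(mme$Ainv, p + q, D)
  }
  templates <- list(data = gen_triplets(TtT), u = gen_triplets(Au), pe = gen_triplets(Ppe))

  pattern <- methods::as(TtT + Au + Ppe, "generalMatrix")
  Dbig <- t_ * D
  Cbig <- methods::as(
    Matrix::forceSymmetric(Matrix::kronecker(matrix(1, t_, t_), pattern)),
    "CsparseMatrix")
  bi <- Cbig@i + 1L
  bj <- rep(seq_len(Dbig), diff(Cbig@p))
  bigkey <- (bj - 1) * Dbig + bi

  blocks <- list()
  for (j in seq_len(t_)) for (k in j:t_) blocks[[length(blocks) + 1L]] <- c(j, k)
  maps <- lapply(templates, function(g) {
    lapply(blocks, function(bk) {
      j <- bk[1]; k <- bk[2]
      sel <- if (j == k) which(g$i <= g$j) else seq_along(g$i)
      key <- (g$j[sel] + (k - 1L) * D - 1) * Dbig + (g$i[sel] + (j - 1L) * D)
      pos <- match(key, bigkey)
      stopifnot(!anyNA(pos))
      list(pos = pos, x = g$x[sel])
    })
  })

  ## seed the numeric slots with identity coefficients (PD) and analyse
  xb <- numeric(length(Cbig@x))
  for (tm in names(maps)) for (b in seq_along(blocks)) {
    if (blocks[[b]][1] == blocks[[b]][2]) {
      m <- maps[[tm]][[b]]
      xb[m$pos] <- xb[m$pos] + m$x
    }
  }
  Cbig@x <- xb
  ch <- Matrix::Cholesky(Cbig, LDL = FALSE, perm = TRUE)

  ## missingness pattern groups for the imputation step
  groups <- NULL
  if (any(!mme$obs)) {
    key <- as.vector(mme$obs %*% 2^(seq_len(t_) - 1))
    groups <- lapply(split(seq_len(mme$n), key), function(rows) {
      ob <- mme$obs[rows[1], ]
      list(rows = rows, obs = which(ob), mis = which(!ob))
    })
    groups <- Filter(function(g) length(g$mis) > 0, groups)
  }

  ws <- list(Tm = Tm, TtT = TtT, Cbig = Cbig, ch = ch, maps = maps,
             blocks = blocks, t_ = t_, D = D, Dbig = Dbig, groups = groups)
  mme$cache$ws <- ws
  ws
}

## record-level linear predictor (n x t)
linear_predictor <- function(state, mme) {
  mme$X %*% state$b + state$u[mme$zrow, , drop = FALSE] +
    state$pe[mme$wrow, , drop = FALSE]
}

#' One Gibbs update of all location effects
#'
#' Draws fixed effects, breeding values and permanent environmental effects
#' jointly from their Gaussian full conditional given the current response
#' matrix and covariance components in `state`.  Fixed effects carry a flat
#' prior, so with the random-effect variances sent to zero their posterior
#' collapses to the GLS/OLS solution.
#'
#' @param state list with elements `y` (complete response matrix), `b`,
#'   `u`, `pe` and the three covariance matrices `sigma_u`, `sigma_pe`,
#'   `sigma_e`.
#' @param mme design object from [build_design_matrices()].
#' @return `state` with updated `b`, `u`, `pe`.
#' @export
sample_location_effects <- function(state, mme) {
  ws <- gibbs_workspace(mme)
  t_ <- ws$t_; D <- ws$D
  Einv <- solve(state$sigma_e)
  Uinv <- solve(state$sigma_u)
  Pinv <- solve(state$sigma_pe)
  coefs <- list(data = Einv, u = Uinv, pe = Pinv)

  xb <- numeric(length(ws$Cbig@x))
  for (tm in names(ws$maps)) {
    cf <- coefs[[tm]]
    for (b in seq_along(ws$blocks)) {
      jk <- ws$blocks[[b]]
      cc <- cf[jk[1], jk[2]]
      if (cc == 0) next
      m <- ws$maps[[tm]][[b]]
      xb[m$pos] <- xb[m$pos] + cc * m$x
    }
  }
  Cbig <- ws$Cbig
  Cbig@x <- xb
  ch <- tryCatch(Matrix::update(ws$ch, Cbig),
                 error = function(e) stop("singular conditional precision for location effects: ",
                                          conditionMessage(e)))
  mme$cache$ws$ch <- ch

  R <- Matrix::crossprod(ws$Tm, state$y %*% Einv)
  r <- as.numeric(as.matrix(R))
  mu <- as.numeric(Matrix::solve(ch, matrix(r, ncol = 1), system = "A"))
  z <- matrix(stats::rnorm(ws$Dbig), ncol = 1)
  dr <- as.numeric(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt"))
  theta <- matrix(mu + dr, D, t_)

  p <- mme$p; q <- mme$q
  state$b <- theta[seq_len(p), , drop = FALSE]
  state$u <- theta[p + seq_len(q), , drop = FALSE]
  state$pe <- theta[p + q + seq_len(mme$pa), , drop = FALSE]
  state
}

#' One Gibbs update of the covariance components
#'
#' Inverse-Wishart full conditionals under flat priors: scale matrices
#' `u'A^-1 u`, `pe'pe` (or `pe'A^-1 pe`) and `e'e` with degrees of freedom
#' `q - t - 1`, `p_a - t - 1` and `n - t - 1` (the improper limit of an
#' inverse-Wishart with prior df `-(t+1)` and zero scale).  In one trait
#' this is the scaled inverse chi-square `S / chisq(n - 2)`.  A positivity
#' floor keeps draws away from the absorbing state at zero; with all
#' residuals zero the draws therefore collapse towards the floor rather
#' than erroring.
#'
#' @inheritParams sample_location_effects
#' @return `state` with updated `sigma_u`, `sigma_pe`, `sigma_e`.
#' @export
sample_variance_components <- function(state, mme) {
  t_ <- length(mme$traits)
  fl <- mme$spec$variance_floor
  df_u <- (mme$q) - t_ - 1
  df_pe <- (if (mme$spec$pe_covariance == "identity") mme$pa else mme$q) - t_ - 1
  df_e <- mme$n - t_ - 1
  if (min(df_u, df_pe, df_e) <= t_ - 1)
    stop("too few animals/records relative to the number of traits for proper ",
         "variance full conditionals")

  S_u <- as.matrix(Matrix::crossprod(state$u, mme$Ainv %*% state$u)) + fl * diag(t_)
  state$sigma_u <- pd_floor(riwish1(S_u, df_u), fl)

  S_pe <- if (mme$spec$pe_covariance == "identity") {
    crossprod(state$pe)
  } else {
    as.matrix(Matrix::crossprod(state$pe, mme$Ainv %*% state$pe))
  }
  state$sigma_pe <- pd_floor(riwish1(S_pe + fl * diag(t_), df_pe), fl)

  E <- state$y - as.matrix(linear_predictor(state, mme))
  state$sigma_e <- pd_floor(riwish1(crossprod(E) + fl * diag(t_), df_e), fl)
  state
}

#' One Gibbs update of the missing trait scores
#'
#' For every missingness pattern, missing entries are drawn from their
#' Gaussian conditional given the record's observed traits and the current
#' parameters; observed entries are never modified.  With a diagonal
#' residual covariance the draw reduces to the record's linear predictor
#' plus independent noise.
#'
#' @inheritParams sample_location_effects
#' @return `state` with imputed `y`.
#' @export
impute_missing_traits <- function(state, mme) {
  ws <- gibbs_workspace(mme)
  if (is.null(ws$groups)) return(state)
  Mu <- as.matrix(linear_predictor(state, mme))
  Se <- state$sigma_e
  for (g in ws$groups) {
    o <- g$obs; m <- g$mis; rows <- g$rows
    if (length(o)) {
      B <- Se[m, o, drop = FALSE] %*% solve(Se[o, o, drop = FALSE])
      condS <- Se[m, m, drop = FALSE] - B %*% Se[o, m, drop = FALSE]
      resid_o <- mme$y[rows, o, drop = FALSE] - Mu[rows, o, drop = FALSE]
      mean_m <- Mu[rows, m, drop = FALSE] + resid_o %*% t(B)
    } else {
      condS <- Se[m, m, drop = FALSE]
      mean_m <- Mu[rows, m, drop = FALSE]
    }
    condS <- (condS + t(condS)) / 2
    state$y[rows, m] <- mean_m + rmvn0(length(rows), condS + 1e-12 * diag(length(m)))
  }
  state
}

#' Fit the animal model by Gibbs sampling
#'
#' Runs the full chain: per iteration missing-score imputation, a joint
#' location-effect draw, and covariance-component draws; saves the
#' covariance matrices after burn-in at the thinning interval.  The run is
#' deterministic given `spec$seed`.
#'
#' @param records phenotype records (one row per evaluation).
#' @param ped sorted pedigree.
#' @param spec a [model_spec()].
#' @return object of class `"gibbs_fit"`: arrays `sigma_u`, `sigma_pe`,
#'   `sigma_e` of dimension traits x traits x draws, posterior means of
#'   `u` and `pe`, optional `b_draws`, and `meta` bookkeeping.
#' @export
run_gibbs <- function(records, ped, spec) {
  mme <- build_design_matrices(records, ped, spec)
  run_gibbs_mme(mme)
}

#' @rdname run_gibbs
#' @param mme prebuilt design object (alternative entry point).
#' @export
run_gibbs_mme <- function(mme) {
  spec <- mme$spec
  t_ <- length(mme$traits)
  set.seed(spec$seed)
  ws <- gibbs_workspace(mme)

  ## initial state: trait means for missing scores, equal variance split
  y0 <- mme$y
  vy <- numeric(t_)
  for (j in seq_len(t_)) {
    obs <- mme$obs[, j]
    mj <- mean(y0[obs, j])
    y0[!obs, j] <- mj
    vy[j] <- max(stats::var(y0[obs, j]), 1e-6)
  }
  state <- list(
    y = y0,
    b = matrix(0, mme$p, t_),
    u = matrix(0, mme$q, t_),
    pe = matrix(0, mme$pa, t_),
    sigma_u = diag(vy / 3, t_, t_),
    sigma_pe = diag(vy / 3, t_, t_),
    sigma_e = diag(vy / 3, t_, t_)
  )

  nsave <- (spec$n_iterations - spec$burn_in) %/% spec$thin
  dn <- list(mme$traits, mme$traits, NULL)
  out_u <- array(NA_real_, c(t_, t_, nsave), dimnames = dn)
  out_pe <- array(NA_real_, c(t_, t_, nsave), dimnames = dn)
  out_e <- array(NA_real_, c(t_, t_, nsave), dimnames = dn)
  b_draws <- if (spec$save_locations) array(NA_real_, c(mme$p, t_, nsave)) else NULL
  u_mean <- matrix(0, mme$q, t_)
  pe_mean <- matrix(0, mme$pa, t_)
  augment <- spec$missing_handling == "augment" && !is.null(ws$groups)

  k <- 0L
  for (it in seq_len(spec$n_iterations)) {
    if (augment) state <- impute_missing_traits(state, mme)
    state <- sample_location_effects(state, mme)
    state <- sample_variance_components(state, mme)
    if (it > spec$burn_in && (it - spec$burn_in) %% spec$thin == 0L) {
      k <- k + 1L
      out_u[, , k] <- state$sigma_u
      out_pe[, , k] <- state$sigma_pe
      out_e[, , k] <- state$sigma_e
      if (!is.null(b_draws)) b_draws[, , k] <- state$b
      u_mean <- u_mean + state$u
      pe_mean <- pe_mean + state$pe
    }
    if (spec$report_every > 0L && it %% spec$report_every == 0L) {
      h2 <- diag(state$sigma_u) / (diag(state$sigma_u) + diag(state$sigma_pe) + diag(state$sigma_e))
      message(sprintf("iteration %d/%d  h2 = %s", it, spec$n_iterations,
                      paste(sprintf("%.3f", h2), collapse = " ")))
    }
  }
  stopifnot(k == nsave)

  fit <- list(
    sigma_u = out_u, sigma_pe = out_pe, sigma_e = out_e,
    b_draws = b_draws,
    u_mean = u_mean / max(1, nsave), pe_mean = pe_mean / max(1, nsave),
    meta = list(spec = spec, traits = mme$traits, n_records = mme$n,
                n_animals = mme$q, n_pe = mme$pa, nsave = nsave,
                seed = spec$seed)
  )
  class(fit) <- "gibbs_fit"
  fit
}

#' @export
print.gibbs_fit <- function(x, ...) {
  m <- x$meta
  cat("Gibbs animal-model fit\n")
  cat("  traits:      ", paste(m$traits, collapse = ", "), "\n")
  cat("  records:     ", m$n_records, " on ", m$n_pe, " animals (pedigree ",
      m$n_animals, ")\n", sep = "")
  cat("  saved draws: ", m$nsave, " (iterations ", m$spec$n_iterations,
      ", burn-in ", m$spec$burn_in, ", thin ", m$spec$thin, ")\n", sep = "")
  h2 <- sapply(seq_along(m$traits), function(j)
    mean(x$sigma_u[j, j, ] / (x$sigma_u[j, j, ] + x$sigma_pe[j, j, ] + x$sigma_e[j, j, ])))
  cat("  posterior mean h2:", paste(sprintf("%s=%.3f", m$traits, h2), collapse = ", "), "\n")
  invisible(x)
}
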