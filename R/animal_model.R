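## Model specification and mixed-model design construction.

#' Specify an animal-model Gibbs run
#'
#' @param traits character vector of response column names (latent scores or
#'   0/1/2 class scores; the model is linear Gaussian either way).
#' @param factors named list of fixed-factor levels, in model order; the
#'   first level of each factor is absorbed into the intercept
#'   (reference-cell coding).  Defaults to the five-factor layout gender(2),
#'   birth period(3), stud criterion(4), age group(2), appraiser(3).
#' @param n_iterations,burn_in,thin chain settings.  Defaults follow the
#'   long-run protocol (250,000 rounds, 50,000 burn-in, every sample saved);
#'   scale them down for tests.
#' @param seed integer seed; the whole run is deterministic given it.
#' @param missing_handling `"augment"` imputes missing trait scores from
#'   their Gaussian conditional each sweep; `"complete_cases"` drops
#'   incomplete records up front.
#' @param pe_covariance `"identity"` (default) gives each recorded animal an
#'   iid permanent environmental effect; `"pedigree"` correlates pe via the
#'   relationship matrix instead.
#' @param variance_floor positivity floor applied to covariance draws so the
#'   chain cannot be absorbed at zero.
#' @param save_locations also save thinned draws of fixed effects (and
#'   sparse subsamples of u and pe).
#' @param report_every print a progress line every so many iterations
#'   (0 = silent).
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(traits,
                       factors = default_factor_levels(),
                       n_iterations = 250000L, burn_in = 50000L, thin = 1L,
                       seed = 1L,
                       missing_handling = c("augment", "complete_cases"),
                       pe_covariance = c("identity", "pedigree"),
                       variance_floor = 1e-8,
                       save_locations = FALSE,
                       report_every = 0L) {
  stopifnot(length(traits) >= 1, burn_in < n_iterations, thin >= 1)
  spec <- list(
    traits = traits, factors = factors,
    n_iterations = as.integer(n_iterations), burn_in = as.integer(burn_in),
    thin = as.integer(thin), seed = as.integer(seed),
    missing_handling = match.arg(missing_handling),
    pe_covariance = match.arg(pe_covariance),
    variance_floor = variance_floor,
    save_locations = isTRUE(save_locations),
    report_every = as.integer(report_every)
  )
  class(spec) <- "model_spec"
  spec
}

#' Build mixed-model design matrices
#'
#' Constructs the record-by-effect incidence matrices of the repeatability
#' animal model: `X` (reference-cell coded fixed effects, full column
#' rank), `Z` (record to pedigree animal), `W` (record to permanent
#' environmental effect), the response matrix with missingness mask, and
#' the sparse inverse relationship matrix.  Records with every trait
#' missing are dropped with a warning; under `complete_cases` any record
#' with a missing trait is dropped.
#'
#' @param records phenotype record data.frame (one row per evaluation).
#' @param ped sorted pedigree containing every record animal.
#' @param spec a [model_spec()].
#' @return list of class `"mme"`.
#' @export
build_design_matrices <- function(records, ped, spec) {
  assert_sorted_ped(ped)
  stopifnot(inherits(spec, "model_spec"))
  traits <- spec$traits
  missing_cols <- setdiff(c(traits, names(spec$factors), "animal"), names(records))
  if (length(missing_cols))
    stop("records lack required column(s): ", paste(missing_cols, collapse = ", "))

  y <- as.matrix(records[, traits, drop = FALSE])
  storage.mode(y) <- "double"
  empty <- colSums(!is.na(y)) == 0L
  if (any(empty)) stop("trait column(s) with no observed scores: ",
                       paste(traits[empty], collapse = ", "))
  keep <- rowSums(!is.na(y)) > 0L
  if (spec$missing_handling == "complete_cases") keep <- rowSums(is.na(y)) == 0L
  if (any(!keep)) {
    warning(sum(!keep), " record(s) dropped (",
            if (spec$missing_handling == "augment") "no observed trait" else "incomplete traits", ")")
    records <- records[keep, , drop = FALSE]
    y <- y[keep, , drop = FALSE]
  }
  n <- nrow(records)
  if (n == 0L) stop("no usable records")

  bad <- setdiff(unique(records$animal), ped$animal)
  if (length(bad)) stop("record animal(s) absent from pedigree: ",
                        paste(utils::head(bad, 5), collapse = ", "))

  ## fixed-effect design, reference-cell coding
  fct <- list()
  for (f in names(spec$factors)) {
    v <- as.character(records[[f]])
    unseen <- setdiff(unique(v[!is.na(v)]), spec$factors[[f]])
    if (length(unseen)) stop("factor ", f, " has undeclared level(s): ",
                             paste(unseen, collapse = ", "))
    if (anyNA(v)) stop("factor ", f, " has missing values")
    fct[[f]] <- factor(v, levels = spec$factors[[f]])
  }
  if (length(fct)) {
    X <- stats::model.matrix(~ ., data = as.data.frame(fct))
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  X <- X[, colSums(abs(X)) > 0, drop = FALSE]   # declared-but-unobserved levels
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    warning("aliased fixed-effect column(s) dropped: ",
            paste(colnames(X)[-keep_cols], collapse = ", "))
    X <- X[, sort(keep_cols), drop = FALSE]
  }

  q <- nrow(ped)
  zrow <- match(records$animal, ped$animal)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = zrow, x = 1, dims = c(n, q))
  if (spec$pe_covariance == "identity") {
    pe_ids <- ped$animal[sort(unique(zrow))]
    wrow <- match(records$animal, pe_ids)
    W <- Matrix::sparseMatrix(i = seq_len(n), j = wrow, x = 1,
                              dims = c(n, length(pe_ids)))
  } else {
    pe_ids <- ped$animal
    wrow <- zrow
    W <- Z
  }

  mme <- list(
    X = X, Z = Z, W = W, y = y, obs = !is.na(y),
    zrow = zrow, wrow = wrow,
    traits = traits, animals = ped$animal, pe_ids = pe_ids,
    n = n, p = ncol(X), q = q, pa = length(pe_ids),
    Ainv = build_A_inverse(ped),
    spec = spec,
    records = records[, c("animal", names(spec$factors)), drop = FALSE],
    cache = new.env(parent = emptyenv())
  )
  class(mme) <- "mme"
  mme
}
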