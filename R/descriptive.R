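## Record-level prevalence tables, multinomial-logit factor screening and
## gait-score comparison across defect classes.

#' Prevalence table for 0/1/2 defect scores
#'
#' Counts records (not animals) per class and reports percentages rounded
#' half away from zero to `digits` decimals.  The combined class 1+2
#' prevalence is reported as the sum of the rounded class-1 and class-2
#' percentages (`pct12`), matching common published-table practice; the
#' unrounded count-based value is kept in `pct12_raw`.  Missing scores are
#' excluded from N; traits with no scored records are omitted with a
#' warning.
#'
#' @param records record data.frame with integer 0/1/2 trait columns.
#' @param traits trait column names (defaults to every column whose
#'   observed values are all in 0/1/2).
#' @param digits percentage rounding.
#' @return data.frame of class `"prevalence_table"`: trait, N, per-class n
#'   and percentages, n12, pct12, pct12_raw.
#' @export
prevalence_table <- function(records, traits = NULL, digits = 2) {
  if (is.null(traits)) {
    is_score <- vapply(records, function(v) {
      is.numeric(v) && any(!is.na(v)) && all(stats::na.omit(v) %in% 0:2)
    }, logical(1))
    is_score[names(records) %in% c("record_id", "walk", "trot")] <- FALSE
    traits <- names(records)[is_score]
  }
  rows <- list()
  for (tr in traits) {
    v <- records[[tr]]
    if (is.null(v)) stop("no such trait column: ", tr)
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("trait ", tr, " has no scored records; omitted")
      next
    }
    if (!all(v %in% 0:2)) stop("trait ", tr, " has scores outside 0/1/2")
    N <- length(v)
    n <- tabulate(v + 1L, nbins = 3L)
    pct <- round_half_up(100 * n / N, digits)
    rows[[tr]] <- data.frame(
      trait = tr, N = N,
      n0 = n[1], pct0 = pct[1], n1 = n[2], pct1 = pct[2], n2 = n[3], pct2 = pct[3],
      n12 = n[2] + n[3],
      pct12 = round_half_up(pct[2] + pct[3], digits),
      pct12_raw = 100 * (n[2] + n[3]) / N)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Prevalence stratified by a non-genetic factor
#'
#' @param records record data.frame.
#' @param factor_name one of the five evaluation factors (or any factor
#'   column present in `records`).
#' @param traits,digits passed to [prevalence_table()].
#' @return named list of prevalence tables, one per factor level present.
#' @export
prevalence_by_factor <- function(records, factor_name, traits = NULL, digits = 2) {
  if (!factor_name %in% names(records)) stop("unknown factor: ", factor_name)
  split_rec <- split(records, records[[factor_name]])
  lapply(split_rec, prevalence_table, traits = traits, digits = digits)
}

## ---- baseline-category multinomial logit --------------------------------

## Newton fit of a baseline-category (class 0) multinomial logit.
## X: n x p design, yf: factor response with >= 2 levels.
## Returns coefficients (p x (C-1)), log-likelihood, convergence flag.
multinom_newton <- function(X, yf, ridge = 0, max_iter = 200, tol = 1e-10) {
  C <- nlevels(yf)
  n <- nrow(X); p <- ncol(X)
  Yi <- diag(C)[as.integer(yf), , drop = FALSE]
  B <- matrix(0, p, C - 1)
  rowmax <- function(m) {
    out <- m[, 1]
    for (j in 2:ncol(m)) out <- pmax(out, m[, j])
    out
  }
  loglik <- function(B) {
    eta <- cbind(0, X %*% B)
    eta <- eta - rowmax(eta)
    sum(eta[cbind(seq_len(n), as.integer(yf))]) - sum(log(rowSums(exp(eta))))
  }
  ll <- loglik(B)
  for (iter in seq_len(max_iter)) {
    eta <- cbind(0, X %*% B)
    eta <- eta - rowmax(eta)
    P <- exp(eta); P <- P / rowSums(P)
    G <- crossprod(X, Yi[, -1, drop = FALSE] - P[, -1, drop = FALSE]) - ridge * B
    if (max(abs(G)) < tol) break
    H <- matrix(0, p * (C - 1), p * (C - 1))
    for (k in seq_len(C - 1)) for (l in k:(C - 1)) {
      w <- P[, k + 1] * ((k == l) - P[, l + 1])
      blk <- crossprod(X, X * w)
      ri <- (k - 1) * p + seq_len(p); ci <- (l - 1) * p + seq_len(p)
      H[ri, ci] <- blk
      if (l != k) H[ci, ri] <- t(blk)
    }
    H <- H + ridge * diag(p * (C - 1))
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step)) {
      H <- H + 1e-6 * diag(p * (C - 1))
      step <- solve(H, as.vector(G))
    }
    sc <- 1
    repeat {
      Bn <- B + sc * matrix(step, p, C - 1)
      lln <- loglik(Bn) - ridge * sum(Bn^2) / 2
      if (lln >= ll - ridge * sum(B^2) / 2 - 1e-12 || sc < 1e-4) break
      sc <- sc / 2
    }
    B <- Bn
    lln_plain <- loglik(B)
    if (abs(lln_plain - ll) < tol && max(abs(G)) < 1e-6) { ll <- lln_plain; break }
    ll <- lln_plain
  }
  list(coef = B, loglik = ll, iterations = iter)
}

#' Multinomial-logit screening of non-genetic factors
#'
#' Fits a baseline-category (class 0) multinomial logit of the 0/1/2 score
#' on the evaluation factors by Newton's method, and tests each factor by
#' a likelihood-ratio drop-one test with `(levels - 1) x (classes - 1)`
#' degrees of freedom (actual estimable-column counts when levels are
#' unobserved).  Outcome classes absent from the data collapse the outcome
#' dimension with a warning; factor levels perfectly predicting a single
#' class are flagged as separation and the fit continues with a small
#' ridge.
#'
#' @param records record data.frame.
#' @param trait trait column with 0/1/2 scores.
#' @param factors factor columns to screen (defaults to the five
#'   evaluation factors present in `records`).
#' @return list of class `"glz_fit"` with per-factor `p_values`,
#'   `lr_stats`, `df`, the full-model coefficients and flags.
#' @export
fit_multinomial_logit <- function(records, trait,
                                  factors = intersect(names(default_factor_levels()),
                                                      names(records))) {
  v <- records[[trait]]
  if (is.null(v)) stop("no such trait column: ", trait)
  keep <- !is.na(v)
  for (f in factors) keep <- keep & !is.na(records[[f]])
  dat <- records[keep, , drop = FALSE]
  v <- v[keep]
  classes <- sort(unique(v))
  if (length(classes) < 2) stop("trait ", trait, " has fewer than 2 observed classes")
  if (length(classes) < 3)
    warning("outcome classes collapsed to observed set {",
            paste(classes, collapse = ","), "} for trait ", trait)
  yf <- factor(v, levels = classes)

  fdat <- lapply(dat[factors], function(x) droplevels(factor(x)))
  separation <- vapply(factors, function(f) {
    tab <- table(fdat[[f]], yf)
    any(rowSums(tab > 0) == 1L & rowSums(tab) > 0)
  }, logical(1))
  ridge <- if (any(separation)) 1e-6 else 0
  if (any(separation))
    warning("possible separation for factor(s) ", paste(factors[separation], collapse = ", "),
            "; using ridge-stabilised Newton")

  build_X <- function(fs) {
    if (!length(fs)) return(matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)")))
    X <- stats::model.matrix(~ ., data = as.data.frame(fdat[fs]))
    X[, colSums(abs(X)) > 0, drop = FALSE]
  }
  X_full <- build_X(factors)
  fit_full <- multinom_newton(X_full, yf, ridge = ridge)

  lr <- df <- pv <- stats::setNames(numeric(length(factors)), factors)
  for (f in factors) {
    X_red <- build_X(setdiff(factors, f))
    fit_red <- multinom_newton(X_red, yf, ridge = ridge)
    lr[f] <- max(0, 2 * (fit_full$loglik - fit_red$loglik))
    df[f] <- (ncol(X_full) - ncol(X_red)) * (length(classes) - 1)
    pv[f] <- stats::pchisq(lr[f], df[f], lower.tail = FALSE)
  }
  structure(list(trait = trait, p_values = pv, lr_stats = lr, df = df,
                 coef = fit_full$coef, loglik = fit_full$loglik,
                 classes = classes, separation = separation, ridge = ridge),
            class = "glz_fit")
}

## ---- one-way gait GLM with Tukey-Kramer letters -------------------------

## Compact letter display by insert-and-absorb over the significant-pair
## constraints; groups are in mean order, letters are assigned in column
## order so the display is invariant to input labelling.
compact_letters <- function(group_names, sig_pairs) {
  cols <- list(group_names)
  for (pr in sig_pairs) {
    newcols <- list()
    for (cl in cols) {
      if (all(pr %in% cl)) {
        newcols <- c(newcols, list(setdiff(cl, pr[1])), list(setdiff(cl, pr[2])))
      } else {
        newcols <- c(newcols, list(cl))
      }
    }
    ## absorb subsets
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
      if (a != b && keep[a] && keep[b] &&
          all(newcols[[a]] %in% newcols[[b]]) &&
          (length(newcols[[a]]) < length(newcols[[b]]) || a > b)) keep[a] <- FALSE
    }
    cols <- unique(newcols[keep])
  }
  ord <- order(vapply(cols, function(cl) min(match(cl, group_names)), numeric(1)))
  cols <- cols[ord]
  out <- vapply(group_names, function(g) {
    paste(letters[which(vapply(cols, function(cl) g %in% cl, logical(1)))], collapse = "")
  }, character(1))
  out
}

#' Gait-score comparison across defect classes
#'
#' One-way fixed-effects linear model of a gait score on the 0/1/2 defect
#' class, with the omnibus F test and Tukey-Kramer pairwise comparisons at
#' `alpha` in their unbalanced-sample form.  Classes with fewer than two
#' records are reported with their mean only and excluded from the
#' pairwise tests.  With two groups the Tukey p-value equals the pooled
#' two-sample t-test p-value.
#'
#' @param records record data.frame.
#' @param trait trait column giving the 0/1/2 grouping.
#' @param gait `"walk"` or `"trot"`.
#' @param alpha significance level for the letter display.
#' @return list of class `"gait_fit"`: per-class `table` (n, mean,
#'   letters), `F`, `p_value`, `pairwise` p-value matrix.
#' @export
fit_gait_glm <- function(records, trait, gait = c("walk", "trot"), alpha = 0.05) {
  gait <- match.arg(gait)
  cl <- records[[trait]]
  sc <- records[[gait]]
  if (is.null(cl)) stop("no such trait column: ", trait)
  keep <- !is.na(cl) & !is.na(sc)
  cl <- cl[keep]; sc <- sc[keep]
  tab <- data.frame(class = sort(unique(cl)))
  tab$n <- vapply(tab$class, function(g) sum(cl == g), numeric(1))
  tab$mean <- vapply(tab$class, function(g) mean(sc[cl == g]), numeric(1))

  usable <- tab$class[tab$n >= 2]
  sub <- cl %in% usable
  g <- factor(cl[sub])
  x <- sc[sub]
  k <- nlevels(g)
  Fstat <- NA_real_; pF <- NA_real_
  pw <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  letters_out <- rep("", nrow(tab))
  if (k >= 2 && length(x) > k) {
    mns <- tapply(x, g, mean)
    ns <- tapply(x, g, length)
    ssb <- sum(ns * (mns - mean(x))^2)
    ssw <- sum((x - mns[g])^2)
    dfr <- length(x) - k
    s2 <- ssw / dfr
    if (s2 > 0) {
      Fstat <- (ssb / (k - 1)) / s2
      pF <- stats::pf(Fstat, k - 1, dfr, lower.tail = FALSE)
    } else {
      ## zero within-group variance: no evidence against equality unless
      ## the group means themselves differ
      Fstat <- if (ssb > 0) Inf else 0
      pF <- if (ssb > 0) 0 else 1
    }
    sig_pairs <- list()
    if (s2 > 0) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        qstat <- abs(mns[a] - mns[b]) / sqrt(s2 / 2 * (1 / ns[a] + 1 / ns[b]))
        pw[a, b] <- pw[b, a] <- stats::ptukey(qstat, nmeans = k, df = dfr, lower.tail = FALSE)
        if (pw[a, b] < alpha) sig_pairs <- c(sig_pairs, list(levels(g)[c(a, b)]))
      }
    } else {
      pw[upper.tri(pw) | lower.tri(pw)] <- 1
    }
    lets <- compact_letters(levels(g), sig_pairs)
    letters_out[match(as.numeric(levels(g)), tab$class)] <- lets
  }
  tab$letters <- letters_out
  structure(list(trait = trait, gait = gait, table = tab,
                 F = Fstat, p_value = pF, pairwise = pw, alpha = alpha),
            class = "gait_fit")
}
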