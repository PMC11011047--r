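## Pedigree construction, validation, inbreeding and relationship matrices.
##
## A pedigree is a data.frame with columns animal, sire, dam (character;
## NA = unknown parent), birth_year (integer or NA) and sex
## ("male"/"female"/"unknown").  validate_and_sort() returns the canonical
## topologically sorted form (class "ped_table") on which all matrix
## routines operate: parents always precede offspring.

#' Assemble a raw pedigree table
#'
#' Convenience constructor putting parentage vectors into the column layout
#' the rest of the package expects.  The result is *not* yet validated or
#' sorted; pass it through [validate_and_sort()].
#'
#' @param animal character vector of animal identifiers.
#' @param sire,dam character vectors of parent identifiers; `NA`, `""` and
#'   `"0"` all denote an unknown parent.
#' @param birth_year integer vector (or `NA`) of birth years, used only as a
#'   sorting tie-break.
#' @param sex character vector, `"male"`, `"female"` or `"unknown"`.
#' @return a data.frame with the five pedigree columns.
#' @export
ped_table <- function(animal, sire = NA, dam = NA, birth_year = NA, sex = "unknown") {
  n <- length(animal)
  data.frame(
    animal = as.character(animal),
    sire = rep_len(as.character(sire), n),
    dam = rep_len(as.character(dam), n),
    birth_year = rep_len(as.integer(birth_year), n),
    sex = rep_len(as.character(sex), n),
    stringsAsFactors = FALSE
  )
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

#' Validate and topologically sort a pedigree
#'
#' Normalises unknown-parent codes to `NA`, materialises phantom parents
#' (identifiers referenced as sire or dam but absent from the table) as
#' founders, and sorts the rows so that every parent precedes its offspring.
#' Ties are broken by birth year (unknown years last) and then by
#' identifier, so the output order is deterministic regardless of input
#' order.
#'
#' @param ped a data.frame as produced by [ped_table()] (columns `animal`,
#'   `sire`, `dam`, and optionally `birth_year`, `sex`).
#' @return the sorted pedigree, a data.frame of class `"ped_table"` with
#'   integer columns `sire_row`/`dam_row` (0 = unknown) giving parent row
#'   positions.
#' @export
validate_and_sort <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("animal", "sire", "dam") %in% names(ped)))
  animal <- as.character(ped$animal)
  if (anyDuplicated(animal))
    stop("duplicate animal_id in pedigree: ", animal[duplicated(animal)][1])
  sire <- normalize_parent(ped$sire)
  dam <- normalize_parent(ped$dam)
  birth_year <- if ("birth_year" %in% names(ped)) as.integer(ped$birth_year) else rep(NA_integer_, length(animal))
  sex <- if ("sex" %in% names(ped)) as.character(ped$sex) else rep("unknown", length(animal))
  sex[is.na(sex)] <- "unknown"

  ## phantom parents become founders
  phantom_s <- setdiff(stats::na.omit(sire), animal)
  phantom_d <- setdiff(stats::na.omit(dam), animal)
  phantom_d <- setdiff(phantom_d, phantom_s)
  if (length(phantom_s) || length(phantom_d)) {
    animal <- c(animal, phantom_s, phantom_d)
    sire <- c(sire, rep(NA_character_, length(phantom_s) + length(phantom_d)))
    dam <- c(dam, rep(NA_character_, length(phantom_s) + length(phantom_d)))
    birth_year <- c(birth_year, rep(NA_integer_, length(phantom_s) + length(phantom_d)))
    sex <- c(sex, rep("male", length(phantom_s)), rep("female", length(phantom_d)))
  }
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal)) {
    bad <- animal[(!is.na(sire) & sire == animal) | (!is.na(dam) & dam == animal)][1]
    stop("cycle in parentage involving animal ", bad)
  }

  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L

  ## Kahn topological sort, deterministic: eligible animals appended in
  ## (birth_year, id) order, unknown years last.
  placed <- logical(n)
  ord <- integer(0)
  key_year <- ifelse(is.na(birth_year), .Machine$integer.max, birth_year)
  while (length(ord) < n) {
    ok_parent <- function(p) p == 0L | placed[pmax(p, 1L)]
    eligible <- which(!placed & ok_parent(si) & ok_parent(di))
    if (!length(eligible)) {
      stop("cycle in parentage involving animal ", animal[which(!placed)[1]])
    }
    eligible <- eligible[order(key_year[eligible], animal[eligible])]
    ord <- c(ord, eligible)
    placed[eligible] <- TRUE
  }

  out <- data.frame(
    animal = animal[ord], sire = sire[ord], dam = dam[ord],
    birth_year = birth_year[ord], sex = sex[ord],
    stringsAsFactors = FALSE
  )
  out$sire_row <- match(out$sire, out$animal)
  out$dam_row <- match(out$dam, out$animal)
  out$sire_row[is.na(out$sire_row)] <- 0L
  out$dam_row[is.na(out$dam_row)] <- 0L
  rownames(out) <- NULL
  class(out) <- c("ped_table", "data.frame")
  out
}

assert_sorted_ped <- function(ped) {
  if (!inherits(ped, "ped_table"))
    stop("pedigree must first be passed through validate_and_sort()")
  invisible(ped)
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes per-animal inbreeding coefficients F (diagonal of the numerator
#' relationship matrix minus one) without forming the dense matrix, using
#' the within-animal ancestor traversal of Meuwissen and Luo.  Unknown
#' parents are treated as unrelated non-inbred founders.
#'
#' @param ped a sorted pedigree from [validate_and_sort()].
#' @return named numeric vector of F coefficients in pedigree order.
#' @export
compute_inbreeding <- function(ped) {
  assert_sorted_ped(ped)
  n <- nrow(ped)
  s <- ped$sire_row
  d <- ped$dam_row
  f <- numeric(n)
  ## Mendelian sampling variance share of each animal (founders 1)
  v <- numeric(n)
  for (i in seq_len(n)) {
    if (s[i] > 0L && d[i] > 0L) {
      v[i] <- 0.5 - 0.25 * (f[s[i]] + f[d[i]])
    } else if (s[i] > 0L || d[i] > 0L) {
      v[i] <- 0.75 - 0.25 * f[max(s[i], d[i])]
    } else {
      v[i] <- 1
    }
    if (s[i] == 0L || d[i] == 0L) {
      f[i] <- 0  # at least one unknown parent: unrelated founder lines
      next
    }
    ## a_ii = sum_j L_ij^2 v_j over i and its ancestors (A = T D T')
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in rev(seq_len(i))) {
      if (L[j] == 0) next
      aii <- aii + L[j]^2 * v[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    f[i] <- aii - 1
  }
  names(f) <- ped$animal
  f
}

#' Dense numerator relationship matrix by the tabular method
#'
#' Builds A with the recursion `a_ij = 0.5 (a_{j,s(i)} + a_{j,d(i)})` for
#' `j < i` and `a_ii = 1 + 0.5 a_{s(i),d(i)}`.  Dense construction is capped
#' because memory grows quadratically; large pedigrees should work with the
#' sparse inverse from [build_A_inverse()] instead.
#'
#' @param ped a sorted pedigree.
#' @param max_order refuse dense construction above this many animals.
#' @return list with `order` (animal ids), `A` (dense symmetric matrix) and
#'   `inbreeding` (diagonal minus 1).
#' @export
build_A <- function(ped, max_order = 3000) {
  assert_sorted_ped(ped)
  n <- nrow(ped)
  if (n > max_order)
    stop("pedigree of ", n, " animals exceeds the dense cap (", max_order,
         "); use build_A_inverse() for the sparse inverse instead")
  s <- ped$sire_row
  d <- ped$dam_row
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      a <- numeric(i - 1L)
      if (s[i] > 0L) a <- a + 0.5 * A[j, s[i]]
      if (d[i] > 0L) a <- a + 0.5 * A[j, d[i]]
      A[j, i] <- a
      A[i, j] <- a
    }
    A[i, i] <- if (s[i] > 0L && d[i] > 0L) 1 + 0.5 * A[s[i], d[i]] else 1
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  list(order = ped$animal, A = A, inbreeding = diag(A) - 1)
}

#' Sparse inverse of the numerator relationship matrix (Henderson's rules)
#'
#' Builds A-inverse directly from the pedigree using Henderson's rules with
#' the inbreeding correction: every animal contributes `1/d_i` blocks where
#' `d_i = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one, and 1 for founders.
#'
#' @param ped a sorted pedigree.
#' @param f inbreeding coefficients in pedigree order; computed via
#'   [compute_inbreeding()] when `NULL`.
#' @return a symmetric sparse [Matrix::dsCMatrix-class] of order
#'   `nrow(ped)`.
#' @export
build_A_inverse <- function(ped, f = NULL) {
  assert_sorted_ped(ped)
  n <- nrow(ped)
  if (is.null(f)) f <- compute_inbreeding(ped)
  if (length(f) != n)
    stop("inbreeding vector has length ", length(f), ", pedigree has ", n, " animals")
  s <- ped$sire_row
  d <- ped$dam_row
  ## triplets: at most 9 entries per animal
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  put <- function(i, j, x) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- x
  }
  for (i in seq_len(n)) {
    di <- if (s[i] > 0L && d[i] > 0L) {
      0.5 - 0.25 * (f[s[i]] + f[d[i]])
    } else if (s[i] > 0L || d[i] > 0L) {
      0.75 - 0.25 * f[max(s[i], d[i])]
    } else 1
    w <- 1 / di
    put(i, i, w)
    for (p in c(s[i], d[i])) {
      if (p > 0L) {
        put(i, p, -w / 2); put(p, i, -w / 2); put(p, p, w / 4)
      }
    }
    if (s[i] > 0L && d[i] > 0L) {
      put(s[i], d[i], w / 4); put(d[i], s[i], w / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii[1:k], j = jj[1:k], x = xx[1:k],
                               dims = c(n, n), dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Pedigree generation depth
#'
#' Depth 0 for founders; otherwise one more than the deepest known parent.
#'
#' @param ped a sorted pedigree.
#' @param evaluated optional character vector of animal ids over which the
#'   summary mean is taken (defaults to all animals).
#' @return list with `depth` (named integer vector), `mean_evaluated` and
#'   `max_depth`.
#' @export
count_generations <- function(ped, evaluated = NULL) {
  assert_sorted_ped(ped)
  n <- nrow(ped)
  depth <- integer(n)
  for (i in seq_len(n)) {
    ps <- c(ped$sire_row[i], ped$dam_row[i])
    ps <- ps[ps > 0L]
    depth[i] <- if (length(ps)) 1L + max(depth[ps]) else 0L
  }
  names(depth) <- ped$animal
  ev <- if (is.null(evaluated)) ped$animal else evaluated
  miss <- setdiff(ev, ped$animal)
  if (length(miss)) stop("evaluated animals not in pedigree: ", paste(utils::head(miss, 3), collapse = ", "))
  list(depth = depth,
       mean_evaluated = mean(depth[ev]),
       max_depth = max(depth))
}
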