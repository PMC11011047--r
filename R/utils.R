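## Small internal helpers shared across modules.

## Round half away from zero (printed tables use commercial rounding,
## base round() is banker's).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Draws n multivariate normal vectors with mean 0 and covariance sigma
## (t x t, PD).  Returns an n x t matrix.
rmvn0 <- function(n, sigma) {
  t_ <- nrow(sigma)
  L <- chol(sigma)
  matrix(stats::rnorm(n * t_), n, t_) %*% L
}

## Inverse-Wishart draw: S is the scale matrix (sum of squares), nu the
## degrees of freedom of the IW density |Sigma|^{-(nu+t+1)/2}
## exp(-tr(S Sigma^{-1})/2).  Requires nu > t - 1.
riwish1 <- function(S, nu) {
  t_ <- nrow(S)
  W <- stats::rWishart(1, df = nu, Sigma = solve(S))[, , 1]
  solve(W)
}

## Force symmetry and a minimum eigenvalue floor on a covariance draw.
pd_floor <- function(S, floor = 1e-8) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < floor) {
    ev$values <- pmax(ev$values, floor)
    S <- ev$vectors %*% (ev$values * t(ev$vectors))
    S <- (S + t(S)) / 2
  }
  S
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Tiny FNV-1a style hash of a character scalar, for tagging output files
## with a configuration fingerprint without external dependencies.
config_hash <- function(x) {
  if (!is.character(x)) x <- jsonlite::toJSON(x, auto_unbox = TRUE)
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}
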