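`%||%` <- function(a, b) if (is.null(a)) b else a

## clamp proportions away from the simplex boundary: beta/Dirichlet
## log-densities diverge at 0/1
clamp01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

#' Dirichlet random draws
#'
#' Draws from a Dirichlet distribution via independent gamma variates.
#'
#' @param n number of draws.
#' @param alpha positive concentration vector.
#' @return an `n x length(alpha)` matrix whose rows sum to 1.
#' @export
rdirichlet <- function(n, alpha) {
  stopifnot(n >= 1, all(alpha > 0))
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  ## guard against full-row underflow at very small concentrations
  g[!is.finite(g)] <- 0
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- rep(alpha / sum(alpha), each = sum(zero))
  g / rowSums(g)
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' Stable fan-out of one master seed to named stages (prior estimation,
#' per-group chains, per-cluster analyses) so that stages can be re-run in
#' isolation and results do not depend on execution order.  The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed master seed (integer).
#' @param tag character tag naming the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) %% 2146483647 + h * 1009) %% 2147483629L) + 1L
}

## additive-log-ratio transform (last category as reference) and inverse,
## vectorized over rows
alr <- function(p) {
  p <- as.matrix(p)
  log(p[, -ncol(p), drop = FALSE] / p[, ncol(p)])
}

alr_inv <- function(y) {
  y <- as.matrix(y)
  e <- cbind(exp(y), 1)
  e / rowSums(e)
}

## closed-form Cholesky of a stack of small SPD matrices C[t, , ] (d = 2 or 3);
## returns an array L[t, , ] lower-triangular
chol_stack <- function(C) {
  d <- dim(C)[2]
  L <- array(0, dim = dim(C))
  L[, 1, 1] <- sqrt(pmax(C[, 1, 1], 1e-12))
  if (d >= 2) {
    L[, 2, 1] <- C[, 2, 1] / L[, 1, 1]
    L[, 2, 2] <- sqrt(pmax(C[, 2, 2] - L[, 2, 1]^2, 1e-12))
  }
  if (d >= 3) {
    L[, 3, 1] <- C[, 3, 1] / L[, 1, 1]
    L[, 3, 2] <- (C[, 3, 2] - L[, 3, 1] * L[, 2, 1]) / L[, 2, 2]
    L[, 3, 3] <- sqrt(pmax(C[, 3, 3] - L[, 3, 1]^2 - L[, 3, 2]^2, 1e-12))
  }
  L
}

## multiply each feature's lower-triangular L[t, , ] by its own noise row
lmult_stack <- function(L, eps) {
  d <- dim(L)[2]
  out <- matrix(0, nrow(eps), d)
  for (a in seq_len(d)) {
    acc <- 0
    for (b in seq_len(a)) acc <- acc + L[, a, b] * eps[, b]
    out[, a] <- acc
  }
  out
}
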