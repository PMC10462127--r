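## ---------------------------------------------------------------------------
## Metropolis-within-Gibbs data-augmentation sampler.
##
## One iteration sweeps four blocks:
##   delta | pi      adaptive random-walk Metropolis on (log delta+, alr(pi_bar))
##   pi    | X,delta exact conjugate beta / Dirichlet draws
##   rho   | X       exact conjugate Dirichlet draw
##   X     | Z,pi,rho multinomial re-allocation of each EC's reads
## The latent block is the expensive one and is refreshed only every
## `latent_update_every` iterations; the other blocks run every iteration
## against the last sampled X.
## ---------------------------------------------------------------------------

#' MCMC configuration
#'
#' @param n_iter total iterations (default 2000).
#' @param burn_in burn-in iterations discarded before summaries (default 500).
#' @param latent_update_every refresh cadence of the latent read allocation
#'   (default 10; 1 re-allocates every iteration).
#' @param seed integer seed; `NULL` draws one from the session RNG.
#' @param hw_alpha significance level of the stationarity diagnostic.
#' @param max_restarts how many doubled-length re-runs are allowed when the
#'   diagnostic keeps failing (default 1).
#' @param store_pi keep the full per-sample splice-proportion chains
#'   (memory-heavy; mainly for validation).
#' @param fix_delta optional `T x V` matrix (or length-`V` vector) pinning the
#'   hyper-parameters; the Metropolis block is then skipped.  Intended for
#'   validation runs against closed-form conditional posteriors.
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 2000, burn_in = 500, latent_update_every = 10,
                        seed = NULL, hw_alpha = 0.05, max_restarts = 1,
                        store_pi = FALSE, fix_delta = NULL) {
  stopifnot(burn_in < n_iter, latent_update_every >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 latent_update_every = as.integer(latent_update_every),
                 seed = seed, hw_alpha = hw_alpha,
                 max_restarts = as.integer(max_restarts),
                 store_pi = isTRUE(store_pi), fix_delta = fix_delta),
            class = "mcmc_config")
}

## default weakly-informative prior when no empirical-Bayes prior is supplied
default_prior <- function() {
  structure(list(mean_log_precision = log(10), sd_log_precision = 2,
                 rho_prior_conc = 1), class = "eb_prior")
}

## precompute the EC structures the sampler loops over:
##  - single: fixed X contribution (T, V, N) from single-member ECs
##  - multi:  per multi-member EC, feature indices, flat (T x V) indices and
##            per-sample counts
prep_ec <- function(ds) {
  T <- length(ds$catalog$feature_ids); V <- length(ds$catalog$versions)
  N <- length(ds$samples)
  single <- array(0, dim = c(T, V, N))
  multi <- list()
  for (e in seq_along(ds$members)) {
    m <- ds$members[[e]]
    if (nrow(m) == 1) {
      single[m[1, 1], m[1, 2], ] <- single[m[1, 1], m[1, 2], ] + ds$counts[e, ]
    } else {
      multi[[length(multi) + 1]] <-
        list(id = e, f = m[, 1], idx = m[, 1] + T * (m[, 2] - 1L),
             counts = ds$counts[e, ])
    }
  }
  list(single = single, multi = multi, totals = colSums(ds$counts),
       T = T, V = V, N = N)
}

## per-sample totals over versions, X array (T, V, N) -> T x N matrix
x_totals <- function(X) {
  d <- dim(X)
  out <- matrix(0, d[1], d[3])
  for (v in seq_len(d[2])) out <- out + matrix(X[, v, ], d[1], d[3])
  out
}

#' Allocate equivalence-class reads to features and splice versions
#'
#' Partitions each EC's reads, per sample, with a single multinomial draw over
#' its members, with member probabilities proportional to
#' `rho(feature) * weight(feature, version)`.  In the bulk model the weight is
#' the per-sample splice proportion divided by the version's effective length;
#' in the single-cell model it is the splice proportion itself.  Single-member
#' ECs are allocated deterministically.
#'
#' @param ds an [ec_dataset()].
#' @param rho `T x N` matrix of per-sample feature relative abundances
#'   (columns are simplices; a vector is recycled across samples).
#' @param weights `T x V x N` array (or `T x V` matrix recycled across
#'   samples) of strictly positive allocation weights for every EC member.
#' @return integer array `T x V x N` of allocated counts; total reads are
#'   conserved exactly per sample.
#' @export
allocate_reads <- function(ds, rho, weights) {
  prep <- prep_ec(ds)
  T <- prep$T; V <- prep$V; N <- prep$N
  if (is.vector(rho)) rho <- matrix(rho, T, N)
  if (length(dim(weights)) == 2) weights <- array(weights, dim = c(T, V, N))
  X <- prep$single
  for (i in seq_len(N)) {
    Wi <- matrix(weights[, , i], T, V)
    rhoi <- rho[, i]
    off <- (i - 1) * T * V
    for (e in prep$multi) {
      ci <- e$counts[i]
      if (ci > 0) {
        p <- rhoi[e$f] * Wi[e$idx]
        s <- sum(p)
        if (!is.finite(s) || s <= 0)
          stop("EC ", e$id, ": all member probabilities are zero")
        X[e$idx + off] <- X[e$idx + off] + rmultinom(1, ci, p)
      }
    }
  }
  stopifnot(all(abs(colSums(matrix(X, T * V, N)) - prep$totals) < 1e-8))
  X
}

#' Conjugate draw of feature relative abundances
#'
#' Samples one per-sample abundance simplex from its Dirichlet full
#' conditional, `Dirichlet(prior_conc + Y_1, ..., prior_conc + Y_T)`.
#'
#' @param y per-feature total counts of one sample.
#' @param prior_conc symmetric Dirichlet prior concentration (> 0).
#' @return a simplex vector of length `length(y)`.
#' @export
sample_rho <- function(y, prior_conc = 1) {
  stopifnot(prior_conc > 0)
  drop(rdirichlet(1, prior_conc + y))
}

#' Conjugate draw of within-feature splice proportions
#'
#' Bulk model: `pi_S ~ Beta(delta_S + X_S, delta_U + X_U)`; single-cell model:
#' `pi ~ Dirichlet(delta_S + X_S, delta_U + X_U, delta_A + X_A)` — both exact
#' conjugate updates given the current latent allocation.
#'
#' @param x allocated counts of one feature in one sample (length 2 or 3).
#' @param delta positive hyper-parameter vector of the same length.
#' @return a simplex vector over the splice versions.
#' @export
sample_pi <- function(x, delta) {
  stopifnot(length(x) == length(delta), all(delta > 0))
  drop(rdirichlet(1, delta + x))
}

## log prior + log Jacobian of the (log delta+, alr(pi_bar)) parameterization:
## Normal on log delta+, flat on pi_bar (Jacobian sum(log pi_bar))
lp_delta_prior <- function(delta, prior) {
  dplus <- rowSums(delta)
  dnorm(log(dplus), prior$mean_log_precision, prior$sd_log_precision,
        log = TRUE) + rowSums(log(delta / dplus))
}

## vectorized over features: delta T x V, Slog T x V with
## Slog[t, v] = sum_i log pi_i(t, v)
lp_delta_vec <- function(delta, Slog, n_samples, prior) {
  dplus <- rowSums(delta)
  ll <- rowSums((delta - 1) * Slog) -
    n_samples * (rowSums(lgamma(delta)) - lgamma(dplus))
  ll + lp_delta_prior(delta, prior)
}

#' Log-posterior density of the hyper-parameters given splice proportions
#'
#' Evaluates `log p(delta | pi)` (up to an additive constant) for one feature:
#' the sum over samples of the beta (2 versions) or Dirichlet (3 versions)
#' log-density of the per-sample proportions, plus the prior in the sampler's
#' working parameterization — Normal on the log precision `log(delta+)`, flat
#' on the group-level mean proportions `pi_bar` (with the corresponding
#' log-Jacobian when `jacobian = TRUE`, as used by the Metropolis step).
#' Proportions are clamped away from the simplex boundary before evaluation.
#'
#' @param delta positive hyper-parameter vector (length 2 or 3).
#' @param pi matrix of per-sample proportions, samples in rows, versions in
#'   columns (a vector is taken as the spliced proportion of a 2-version
#'   model).
#' @param prior a prior object (see [estimate_eb_prior()]); default weak.
#' @param jacobian include the log-Jacobian of the transformed scale.
#' @return a finite scalar log density.
#' @export
log_posterior_delta <- function(delta, pi, prior = default_prior(),
                                jacobian = TRUE) {
  stopifnot(all(delta > 0))
  if (is.vector(pi) && length(delta) == 2) pi <- cbind(pi, 1 - pi)
  pi <- clamp01(as.matrix(pi))
  stopifnot(ncol(pi) == length(delta))
  Slog <- matrix(colSums(log(pi)), 1)
  delta <- matrix(delta, 1)
  ll <- rowSums((delta - 1) * Slog) -
    nrow(pi) * (rowSums(lgamma(delta)) - lgamma(rowSums(delta)))
  dplus <- sum(delta)
  out <- ll + dnorm(log(dplus), prior$mean_log_precision,
                    prior$sd_log_precision, log = TRUE)
  if (jacobian) out <- out + sum(log(delta / dplus))
  drop(out)
}

## ---------------------------------------------------------------------------
## adaptive random-walk Metropolis kernel (vectorized over features)
## ---------------------------------------------------------------------------

## state of the Haario-style adaptation: running mean and raw covariance
## accumulator of the transformed chain, one entry per feature
amh_init <- function(n_units, d, init_sd = 0.1) {
  list(n = 0, mean = matrix(0, n_units, d),
       M = array(0, dim = c(n_units, d, d)),
       d = d, init_sd = init_sd, frozen = FALSE, accepts = rep(0, n_units),
       steps = 0)
}

## Welford update of mean and covariance accumulator with the current state x
amh_adapt <- function(state, x) {
  if (state$frozen) return(state)
  state$n <- state$n + 1
  dold <- x - state$mean
  state$mean <- state$mean + dold / state$n
  dnew <- x - state$mean
  d <- state$d
  for (a in seq_len(d)) for (b in seq_len(d))
    state$M[, a, b] <- state$M[, a, b] + dold[, a] * dnew[, b]
  state
}

## proposal covariance: scaled empirical covariance + jitter once enough
## history has accumulated, a fixed diagonal before that
amh_proposal_cov <- function(state) {
  d <- state$d; nu <- nrow(state$mean)
  C <- array(0, dim = c(nu, d, d))
  if (state$n > 50) {
    C <- state$M / (state$n - 1) * (2.38^2 / d)
    for (a in seq_len(d)) C[, a, a] <- C[, a, a] + 1e-6
  } else {
    for (a in seq_len(d)) C[, a, a] <- state$init_sd^2
  }
  C
}

## one vectorized Metropolis step: x (units x d), lp_fun(x_matrix) -> lp vector
amh_step <- function(state, x, lp_cur, lp_fun) {
  L <- chol_stack(amh_proposal_cov(state))
  nu <- nrow(x); d <- state$d
  eps <- matrix(rnorm(nu * d), nu, d)
  xp <- x + lmult_stack(L, eps)
  lp_p <- lp_fun(xp)
  lr <- lp_p - lp_cur
  acc <- is.finite(lp_p) & (log(runif(nu)) < lr)
  x[acc, ] <- xp[acc, ]
  lp_cur[acc] <- lp_p[acc]
  state$accepts <- state$accepts + acc
  state$steps <- state$steps + 1
  state <- amh_adapt(state, x)
  list(state = state, x = x, lp = lp_cur, accepted = acc)
}

#' One adaptive Metropolis update of the hyper-parameters
#'
#' Performs a single random-walk Metropolis step for every feature's
#' `delta`, proposing on the transformed scale
#' `(log delta+, alr(pi_bar))` with a per-feature adaptive covariance, and
#' accepting with the exact ratio of [log_posterior_delta()] densities
#' (non-finite proposals are auto-rejected).
#'
#' @param delta current `T x V` matrix of positive hyper-parameters.
#' @param pi per-sample proportions: `T x V x N` array (or `N x V` matrix for
#'   a single feature).
#' @param prior prior object.
#' @param state adaptation state from a previous call, or `NULL` to start one.
#' @return list with `delta`, `accepted` (logical per feature) and `state`.
#' @export
sample_delta_mh <- function(delta, pi, prior = default_prior(), state = NULL) {
  if (is.matrix(pi) && is.vector(delta)) {        # single feature, N x V
    pi <- aperm(array(t(pi), dim = c(ncol(pi), 1, nrow(pi))), c(2, 1, 3))
    delta <- matrix(delta, 1)
  }
  T <- nrow(delta); V <- ncol(delta); N <- dim(pi)[3]
  Slog <- matrix(0, T, V)
  for (i in seq_len(N)) Slog <- Slog + log(clamp01(matrix(pi[, , i], T, V)))
  if (is.null(state)) state <- amh_init(T, V)
  x <- cbind(log(rowSums(delta)), alr(delta / rowSums(delta)))
  lp_fun <- function(xm) {
    dp <- exp(xm[, 1])
    pb <- alr_inv(xm[, -1, drop = FALSE])
    lp_delta_vec(dp * pb, Slog, N, prior)
  }
  st <- amh_step(state, x, lp_fun(x), lp_fun)
  dp <- exp(st$x[, 1]); pb <- alr_inv(st$x[, -1, drop = FALSE])
  list(delta = dp * pb, accepted = st$accepted, state = st$state)
}

## ---------------------------------------------------------------------------
## full chain
## ---------------------------------------------------------------------------

## one complete MCMC run (no convergence escalation); returns raw chains
run_chain_once <- function(ds, prior, model, n_iter, burn_in,
                           latent_update_every, store_pi, fix_delta, seed) {
  set.seed(seed)
  prep <- prep_ec(ds)
  T <- prep$T; V <- prep$V; N <- prep$N
  bulk <- identical(model, "bulk")
  len <- if (bulk) catalog_len(ds$catalog) else NULL

  ## --- initialization ------------------------------------------------------
  ## X: equal split of every EC count among its members
  X <- prep$single
  for (e in prep$multi) {
    k <- length(e$idx)
    for (i in seq_len(N)) if (e$counts[i] > 0) {
      add <- rep(e$counts[i] %/% k, k)
      r <- e$counts[i] %% k
      if (r > 0) add[seq_len(r)] <- add[seq_len(r)] + 1
      X[e$idx + (i - 1) * T * V] <- X[e$idx + (i - 1) * T * V] + add
    }
  }
  Y <- x_totals(X)
  ## pi: posterior mean under a unit prior
  pi <- array(0, dim = c(T, V, N))
  for (i in seq_len(N)) for (v in seq_len(V))
    pi[, v, i] <- (X[, v, i] + 1) / (Y[, i] + V)
  ## delta: EB prior precision at the pooled naive proportions
  pooled <- matrix(0, T, V)
  for (i in seq_len(N)) pooled <- pooled + matrix(X[, , i], T, V)
  pibar0 <- clamp01((pooled + 0.5) / rowSums(pooled + 0.5), 1e-6)
  pibar0 <- pibar0 / rowSums(pibar0)
  delta <- exp(prior$mean_log_precision) * pibar0
  fixed <- !is.null(fix_delta)
  if (fixed) {
    fd <- if (is.vector(fix_delta)) matrix(fix_delta, T, V, byrow = TRUE)
    else as.matrix(fix_delta)
    stopifnot(all(dim(fd) == c(T, V)), all(fd > 0))
    delta <- fd
  }
  ## rho: posterior mean given the initial totals
  rho <- apply(Y + prior$rho_prior_conc, 2, function(a) a / sum(a))
  rho <- matrix(rho, T, N)

  amh <- amh_init(T, V)
  pibar_chain <- array(NA_real_, dim = c(n_iter, T, V))
  dplus_chain <- matrix(NA_real_, n_iter, T)
  lp_chain <- numeric(n_iter)
  pi_chain <- if (store_pi) array(NA_real_, dim = c(n_iter, T, V, N)) else NULL

  for (it in seq_len(n_iter)) {
    ## ---- delta | pi (adaptive Metropolis) ---------------------------------
    Slog <- matrix(0, T, V)
    for (i in seq_len(N)) Slog <- Slog + log(clamp01(matrix(pi[, , i], T, V)))
    if (!fixed) {
      lp_fun <- function(xm) {
        dp <- exp(xm[, 1])
        pb <- alr_inv(xm[, -1, drop = FALSE])
        lp_delta_vec(dp * pb, Slog, N, prior)
      }
      if (it == burn_in + 1) amh$frozen <- TRUE
      x <- cbind(log(rowSums(delta)), alr(delta / rowSums(delta)))
      st <- amh_step(amh, x, lp_fun(x), lp_fun)
      amh <- st$state
      dp <- exp(st$x[, 1]); pb <- alr_inv(st$x[, -1, drop = FALSE])
      delta <- dp * pb
      lp_chain[it] <- sum(st$lp)
    } else {
      lp_chain[it] <- sum(lp_delta_vec(delta, Slog, N, prior))
    }

    ## ---- pi | X, delta (conjugate) ----------------------------------------
    for (i in seq_len(N)) {
      alpha <- delta + matrix(X[, , i], T, V)
      g <- matrix(rgamma(T * V, shape = alpha), T, V)
      g <- pmax(g, 1e-300)
      pi[, , i] <- g / rowSums(g)
    }

    ## ---- rho | X (conjugate) ----------------------------------------------
    for (i in seq_len(N)) {
      g <- rgamma(T, shape = prior$rho_prior_conc + Y[, i])
      g <- pmax(g, 1e-300)
      rho[, i] <- g / sum(g)
    }

    ## ---- X | Z, pi, rho (latent allocation, undersampled) -----------------
    if (it %% latent_update_every == 0 && length(prep$multi) > 0) {
      X <- prep$single
      for (i in seq_len(N)) {
        Wi <- matrix(pi[, , i], T, V)
        if (bulk) Wi <- Wi / len
        rhoi <- rho[, i]
        off <- (i - 1) * T * V
        for (e in prep$multi) {
          ci <- e$counts[i]
          if (ci > 0) {
            p <- rhoi[e$f] * Wi[e$idx]
            s <- sum(p)
            if (!is.finite(s) || s <= 0)
              stop("EC ", e$id, ": all member probabilities are zero")
            X[e$idx + off] <- X[e$idx + off] + rmultinom(1, ci, p)
          }
        }
      }
      ## read-count conservation is structural; fail loudly if it ever breaks
      if (any(abs(colSums(matrix(X, T * V, N)) - prep$totals) > 1e-8))
        stop("internal error: allocated reads not conserved")
      Y <- x_totals(X)
    }

    dplus <- rowSums(delta)
    pibar_chain[it, , ] <- delta / dplus
    dplus_chain[it, ] <- dplus
    if (store_pi) pi_chain[it, , , ] <- pi
  }

  list(pi_bar = pibar_chain, delta_plus = dplus_chain, lp_trace = lp_chain,
       pi = pi_chain, accept_rate = amh$accepts / max(amh$steps, 1),
       X_final = X, n_iter = n_iter)
}

#' Run the Metropolis-within-Gibbs chain for one group of samples
#'
#' Runs the four-block sampler on one group's equivalence-class counts, then
#' applies the convergence protocol: a Heidelberger–Welch stationarity test on
#' the post-burn-in trace of `log p(delta | pi)`; on failure the burn-in is
#' escalated to half the chain length; if that also fails (and
#' `max_restarts` allows) one fresh chain with doubled length and burn-in is
#' run; a chain still failing is returned flagged as non-converged.
#'
#' @param ds an [ec_dataset()] whose samples all belong to one group.
#' @param config an [mcmc_config()].
#' @param prior an `eb_prior` (see [estimate_eb_prior()]); default weak.
#' @param model `"bulk"` (beta-binomial, length-normalized allocation) or
#'   `"sc"` (Dirichlet-multinomial, no length normalization); inferred from
#'   the catalog mode when `NULL`.
#' @return an object of class `group_posterior` with full chains of the
#'   group-level proportions `pi_bar` and precisions `delta+`, the
#'   log-posterior trace, the final burn-in, acceptance rates and convergence
#'   metadata.
#' @export
run_chain <- function(ds, config = mcmc_config(), prior = NULL, model = NULL) {
  if (is.null(model))
    model <- if (ds$catalog$mode == "bulk-transcript") "bulk" else "sc"
  if (is.null(prior)) prior <- default_prior()
  seed <- config$seed %||% sample.int(2147483600L, 1)
  n_iter <- config$n_iter; burn_in <- config$burn_in

  hw_try <- function(raw, b) {
    tr <- raw$lp_trace[(b + 1):raw$n_iter]
    if (length(tr) < 50)
      return(list(passed = NA, start_index = 1L, skipped = TRUE))
    heidelberger_welch(tr, config$hw_alpha)
  }

  raw <- run_chain_once(ds, prior, model, n_iter, burn_in,
                        config$latent_update_every, config$store_pi,
                        config$fix_delta, seed)
  b <- burn_in
  hw <- hw_try(raw, b)
  escalated <- FALSE; restarted <- FALSE
  restarts_left <- config$max_restarts
  while (isFALSE(hw$passed)) {
    b2 <- floor(raw$n_iter / 2)
    if (b < b2) {
      escalated <- TRUE
      b <- b2
      hw <- hw_try(raw, b)
      if (!isFALSE(hw$passed)) break
    }
    if (restarts_left > 0) {
      restarted <- TRUE
      restarts_left <- restarts_left - 1
      n_iter <- n_iter * 2L
      b <- burn_in * 2L
      raw <- run_chain_once(ds, prior, model, n_iter, b,
                            config$latent_update_every, config$store_pi,
                            config$fix_delta, derive_seed(seed, "restart"))
      hw <- hw_try(raw, b)
    } else break
  }
  converged <- if (is.na(hw$passed %||% NA)) NA else isTRUE(hw$passed)

  structure(list(pi_bar = raw$pi_bar, delta_plus = raw$delta_plus,
                 lp_trace = raw$lp_trace, pi = raw$pi,
                 accept_rate = raw$accept_rate, X_final = raw$X_final,
                 n_iter = raw$n_iter, burn_in = b,
                 converged = converged, hw = hw,
                 hw_escalated = escalated, restarted = restarted,
                 model = model, catalog = ds$catalog, samples = ds$samples,
                 prior = prior, seed = seed, config = config),
            class = "group_posterior")
}

#' @export
print.group_posterior <- function(x, ...) {
  cat("<group_posterior> ", x$model, " model, ",
      length(x$catalog$feature_ids), " features, ", length(x$samples),
      " samples\n  iterations ", x$n_iter, " (burn-in ", x$burn_in,
      "), converged: ", format(x$converged),
      if (x$hw_escalated) ", burn-in escalated",
      if (x$restarted) ", chain restarted", "\n", sep = "")
  invisible(x)
}

#' Post-burn-in chain of the comparison parameter
#'
#' Returns the chain of the unspliced comparison parameter per feature:
#' the group-level unspliced proportion for the bulk model, and
#' `pi_bar_U + 0.5 * pi_bar_A` for the single-cell model (half of the
#' ambiguous mass counted as unspliced).
#'
#' @param gp a `group_posterior`.
#' @return matrix, post-burn-in iterations x features, values in `[0, 1]`.
#' @export
pi_tilde_u <- function(gp) {
  keep <- (gp$burn_in + 1):gp$n_iter
  u <- matrix(gp$pi_bar[keep, , 2], length(keep))
  if (gp$model == "sc") u <- u + 0.5 * matrix(gp$pi_bar[keep, , 3], length(keep))
  colnames(u) <- gp$catalog$feature_ids
  u
}

## post-burn-in chains of (pi_bar_S, pi_bar_U) for the Wald test
pi_bar_su <- function(gp) {
  keep <- (gp$burn_in + 1):gp$n_iter
  list(S = matrix(gp$pi_bar[keep, , 1], length(keep)),
       U = matrix(gp$pi_bar[keep, , 2], length(keep)))
}
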