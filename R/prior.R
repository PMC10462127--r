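## ---------------------------------------------------------------------------
## Empirical-Bayes prior for the hyper-parameters.
##
## The precision delta+ of a feature governs the sample-to-sample variability
## of its splice proportions; it maps one-to-one to the intraclass
## correlation rho = 1 / (1 + delta+) of the beta-binomial /
## Dirichlet-multinomial.  Before running the MCMC we estimate rho per
## feature, for a random subset of features, with a weighted moment estimator
## carrying a finite-sample correction (maximum likelihood at 3-6 replicates
## systematically overstates the precision), and turn the estimates into a
## Normal prior on log(delta+).  Each feature contributes a tiny fraction of
## the prior, so the approach is deliberately mild.
## ---------------------------------------------------------------------------

## naive per-feature counts: every EC count split equally among its members
naive_counts <- function(ds) {
  prep <- prep_ec(ds)
  X <- prep$single
  for (e in prep$multi) {
    k <- length(e$idx)
    for (i in seq_len(prep$N))
      X[e$idx + (i - 1) * prep$T * prep$V] <-
        X[e$idx + (i - 1) * prep$T * prep$V] + e$counts[i] / k
  }
  X
}

## Kleinman-type weighted moment estimate of the intraclass correlation for
## one binomial collapse: proportions p_i = x_i / y_i with weights y_i;
## E[sum w (p - pbar)^2] = pbar qbar [ rho (sum w - sum w^2 / sum w) + (n-1) ]
icc_moment_one <- function(x, y) {
  use <- y > 0
  if (sum(use) < 2) return(NA_real_)
  x <- x[use]; y <- y[use]
  n <- length(y)
  p <- x / y
  pbar <- sum(y * p) / sum(y)
  if (pbar <= 0 || pbar >= 1) return(NA_real_)
  S <- sum(y * (p - pbar)^2)
  denom <- sum(y) - sum(y^2) / sum(y)
  if (denom <= 0) return(NA_real_)
  (S / (pbar * (1 - pbar)) - (n - 1)) / denom
}

## per-feature ICC: average over the binomial collapses of each splice
## version against the rest (identical for the 2-version model)
feature_icc <- function(x) {
  y <- rowSums(x)
  r <- vapply(seq_len(ncol(x)), function(v) icc_moment_one(x[, v], y),
              numeric(1))
  r <- r[is.finite(r)]
  if (!length(r)) return(NA_real_)
  min(max(mean(r), 1 / (1 + 1e6)), 1 / (1 + 1e-2))
}

#' Empirical-Bayes prior on the precision hyper-parameter
#'
#' Selects up to `n_features` features at random, estimates each feature's
#' sample-to-sample precision `delta+` from naive counts (multi-mapping EC
#' counts split equally among members — initialization only) via the
#' moment estimator of the intraclass correlation, and summarizes the
#' estimates into a Normal prior `log(delta+) ~ N(mean, sd)`; the group-level
#' mean proportions keep a flat prior.  The prior mean is the transform of
#' the average intraclass correlation (averaging on the correlation scale
#' avoids the upward bias that per-feature precision estimates carry at few
#' replicates); the sd is floored at 0.5 so the prior never collapses to a
#' point, and individual estimates are bounded to `delta+` in
#' `[1e-2, 1e6]`.
#'
#' @param ds an [ec_dataset()] (typically both groups pooled).
#' @param n_features number of features to sample (default 1000).
#' @param seed integer seed for the feature selection.
#' @return an object of class `eb_prior`: `mean_log_precision`,
#'   `sd_log_precision`, `rho_prior_conc` and the per-feature
#'   `log_precisions`.
#' @export
estimate_eb_prior <- function(ds, n_features = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- length(ds$catalog$feature_ids)
  sel <- sort(sample.int(T, min(n_features, T)))
  X <- naive_counts(ds)
  N <- dim(X)[3]
  icc <- vapply(sel, function(t)
    feature_icc(t(matrix(X[t, , ], dim(X)[2], N))), numeric(1))
  icc <- icc[is.finite(icc)]
  if (length(icc) < 10) {
    warning("fewer than 10 usable features; falling back to a weak prior")
    return(default_prior())
  }
  lp <- log(1 / icc - 1)
  m <- log(1 / mean(icc) - 1)
  s <- max(sd(lp), 0.5)
  structure(list(mean_log_precision = m, sd_log_precision = s,
                 rho_prior_conc = 1, log_precisions = lp,
                 n_features = length(icc)),
            class = "eb_prior")
}

#' @export
print.eb_prior <- function(x, ...) {
  cat("<eb_prior> log(delta+) ~ N(", signif(x$mean_log_precision, 4), ", ",
      signif(x$sd_log_precision, 4), "^2); rho ~ Dirichlet(",
      x$rho_prior_conc, ")\n", sep = "")
  invisible(x)
}
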