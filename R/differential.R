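## ---------------------------------------------------------------------------
## Group comparison: posterior probability of up-regulation, Wald test,
## ranking and result tables.
## ---------------------------------------------------------------------------

#' Posterior probability that group B is up-regulated
#'
#' Estimates `p = Pr(pi_tilde_U_B > pi_tilde_U_A)` from the two posterior
#' chains.  By default the chains are compared at matched iterations
#' (truncated to the shorter length); ties count 1/2, so identical chains
#' give exactly 0.5 and `p(A,B) = 1 - p(B,A)` holds exactly.  With
#' `all_pairs = TRUE` the Mann–Whitney estimator over all chain pairs is used
#' instead.
#'
#' @param chain_a,chain_b numeric post-burn-in chains of the comparison
#'   parameter in groups A and B.
#' @param all_pairs use the all-pairs estimator.
#' @return probability in `[0, 1]`.
#' @export
prob_up_regulated <- function(chain_a, chain_b, all_pairs = FALSE) {
  if (length(chain_a) == 0 || length(chain_b) == 0)
    stop("empty posterior chain")
  if (all_pairs) {
    na <- length(chain_a); nb <- length(chain_b)
    r <- rank(c(chain_b, chain_a))           # midranks handle ties as 1/2
    (sum(r[seq_len(nb)]) - nb * (nb + 1) / 2) / (na * nb)
  } else {
    m <- min(length(chain_a), length(chain_b))
    a <- chain_a[seq_len(m)]; b <- chain_b[seq_len(m)]
    mean((b > a) + 0.5 * (b == a))
  }
}

## Wald statistic from posterior moments; ridge-regularizes a singular
## summed covariance
wald_from_moments <- function(m_a, m_b, S_a, S_b) {
  d <- m_a - m_b
  S <- S_a + S_b
  if (length(d) == 1) {
    S <- as.numeric(S)
    if (S <= 0) S <- S + 1e-8
    stat <- d^2 / S
  } else {
    ok <- is.finite(rcond(S)) && rcond(S) > 1e-12
    if (!ok) {
      warning("singular posterior covariance; applying ridge regularization")
      S <- S + diag(1e-8 * sum(diag(S)) + 1e-12, nrow(S))
    }
    stat <- drop(t(d) %*% solve(S, d))
  }
  stat <- max(stat, 0)
  list(statistic = stat,
       pvalue = pchisq(stat, df = length(d), lower.tail = FALSE))
}

#' Wald test on group-level splice proportions
#'
#' Approximates each group's posterior of the group-level proportions by a
#' normal with the posterior mean and sample covariance of the chains, and
#' tests equality across groups with
#' `T = (m_A - m_B)' (S_A + S_B)^{-1} (m_A - m_B)` against a chi-square with
#' as many degrees of freedom as retained coordinates.  For the single-cell
#' model the retained coordinates are `(pi_bar_S, pi_bar_U)` (the ambiguous
#' proportion is determined by them); for the bulk model `pi_bar_S + pi_bar_U
#' = 1`, so the equivalent univariate test on `pi_bar_U` is performed.
#'
#' @param chains_a,chains_b matrices of post-burn-in draws (iterations x
#'   coordinates); one column for bulk, two for single-cell.
#' @return list with `statistic` (>= 0) and `pvalue`.
#' @export
wald_test <- function(chains_a, chains_b) {
  chains_a <- as.matrix(chains_a); chains_b <- as.matrix(chains_b)
  if (nrow(chains_a) < 2 || nrow(chains_b) < 2)
    stop("need at least 2 posterior draws per group")
  if (nrow(chains_a) < 100 || nrow(chains_b) < 100)
    warning("fewer than 100 posterior draws; Wald approximation is crude")
  wald_from_moments(colMeans(chains_a), colMeans(chains_b),
                    cov(chains_a), cov(chains_b))
}

#' Per-feature differential-regulation results for two fitted groups
#'
#' Builds the result table from two `group_posterior` objects: the posterior
#' probability `p` that group B is up-regulated, the ranking score
#' `max(p, 1 - p)`, the Wald statistic and p-value (with
#' Benjamini–Hochberg adjustment), the posterior means of the comparison
#' parameter in each group, and the convergence flag.
#'
#' @param gp_a,gp_b `group_posterior` objects from [run_chain()] over the
#'   same catalog.
#' @param all_pairs passed to [prob_up_regulated()].
#' @return a `data.frame`, one row per feature.
#' @export
test_differential <- function(gp_a, gp_b, all_pairs = FALSE) {
  stopifnot(identical(gp_a$catalog$feature_ids, gp_b$catalog$feature_ids))
  ua <- pi_tilde_u(gp_a); ub <- pi_tilde_u(gp_b)
  m <- min(nrow(ua), nrow(ub))
  T <- ncol(ua)
  if (all_pairs) {
    p <- vapply(seq_len(T), function(t)
      prob_up_regulated(ua[, t], ub[, t], all_pairs = TRUE), numeric(1))
  } else {
    A <- ua[seq_len(m), , drop = FALSE]; B <- ub[seq_len(m), , drop = FALSE]
    p <- colMeans((B > A) + 0.5 * (B == A))
  }

  sc <- gp_a$model == "sc"
  sa <- pi_bar_su(gp_a); sb <- pi_bar_su(gp_b)
  wald <- vapply(seq_len(T), function(t) {
    ca <- if (sc) cbind(sa$S[, t], sa$U[, t]) else cbind(sa$U[, t])
    cb <- if (sc) cbind(sb$S[, t], sb$U[, t]) else cbind(sb$U[, t])
    w <- wald_test(ca, cb)
    c(w$statistic, w$pvalue)
  }, numeric(2))

  data.frame(
    feature_id = gp_a$catalog$feature_ids,
    p = p,
    rank_score = pmax(p, 1 - p),
    wald_stat = wald[1, ],
    wald_pvalue = wald[2, ],
    bh_pvalue = p.adjust(wald[2, ], method = "BH"),
    mean_piU_A = colMeans(ua),
    mean_piU_B = colMeans(ub),
    converged = rep(gp_a$converged & gp_b$converged, T),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Rank a result table
#'
#' Two ranking modes: `"probability"` orders by `max(p, 1 - p)` decreasing
#' (results with `p` near 0 or 1 first, `p` near 0.5 last); `"wald"` orders
#' by the Wald p-value increasing.  Ties are broken by feature identifier, so
#' the ordering is fully deterministic.
#'
#' @param results a result table from [test_differential()] (or
#'   [summary.diffreg_fit()]).
#' @param by ranking mode.
#' @return the table reordered, with a `rank` column prepended.
#' @export
rank_results <- function(results, by = c("probability", "wald")) {
  by <- match.arg(by)
  if (nrow(results) == 0) stop("empty result table")
  o <- if (by == "probability")
    order(-results$rank_score, results$feature_id)
  else
    order(results$wald_pvalue, results$feature_id)
  out <- results[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write a result table as TSV
#'
#' @param results result table.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
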