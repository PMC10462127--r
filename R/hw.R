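## Bartlett lag-window estimate of the spectral density at frequency zero
## (long-run variance) of a trace; bandwidth ~ sqrt(n) lags
spectral0 <- function(y) {
  n <- length(y)
  L <- min(n - 1, max(5, floor(sqrt(n))))
  y <- y - mean(y)
  g <- drop(stats::acf(y, lag.max = L, type = "covariance",
                       plot = FALSE)$acf)
  w <- 1 - seq_len(L) / (L + 1)
  max(g[1] + 2 * sum(w * g[-1]), 1e-300)
}

#' Heidelberger–Welch stationarity test
#'
#' Stationarity diagnostic for an MCMC trace: the Cramér–von Mises statistic
#' of the Brownian-bridge functional of the cumulative trace, with the
#' long-run variance estimated by the spectral density at frequency zero
#' (Bartlett lag window, bandwidth of about `sqrt(n)` lags).  If the full
#' trace fails at level `alpha`, 10% prefixes are discarded iteratively up to
#' 50% of the trace; the test passes as soon as a retained suffix looks
#' stationary.  A trace with (numerically) zero variance is stationary by
#' definition and passes.
#'
#' @param trace numeric MCMC trace of length >= 50.
#' @param alpha significance level of the test (default 0.05).
#' @return list with `passed` (logical), `start_index` (first retained
#'   iteration of the stationary portion, `NA` when the test fails) and
#'   `pvalue` (of the last portion examined).
#' @export
heidelberger_welch <- function(trace, alpha = 0.05) {
  trace <- as.numeric(trace)
  n1 <- length(trace)
  if (n1 < 50)
    stop("trace too short for the stationarity test (need >= 50, got ", n1, ")")
  if (!all(is.finite(trace))) stop("trace contains non-finite values")
  if (sd(trace) < 1e-12 * (1 + abs(mean(trace))))
    return(list(passed = TRUE, start_index = 1L, pvalue = NA_real_))
  starts <- unique(as.integer(1 + floor(n1 * seq(0, 0.5, by = 0.1))))
  starts <- starts[starts <= n1 - 49]
  pv <- NA_real_
  for (s in starts) {
    y <- trace[s:n1]
    n <- length(y)
    S0 <- spectral0(y)
    B <- cumsum(y) - mean(y) * seq_len(n)
    I <- sum(B^2) / (n^2 * S0)
    pv <- 1 - coda::pcramer(I)
    if (pv > alpha)
      return(list(passed = TRUE, start_index = s, pvalue = pv))
  }
  list(passed = FALSE, start_index = NA_integer_, pvalue = pv)
}
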