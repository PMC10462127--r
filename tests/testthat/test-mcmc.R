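test_that("allocation follows rho * weight probabilities and conserves reads", {
  # one EC compatible with (w, spliced) and (z, unspliced)
  cat0 <- feature_catalog(c("w", "z"), "bulk-transcript")
  samples <- "s1"
  ds <- ec_dataset(cat0, samples, c(s1 = "A"),
                   list(cbind(c(1L, 2L), c(1L, 2L))),
                   matrix(10000, 1, 1))
  rho <- matrix(c(0.5, 0.5), 2, 1)
  w <- matrix(0, 2, 2); w[1, 1] <- 0.8; w[2, 2] <- 0.4
  # member probabilities 0.5*0.8 : 0.5*0.4 = 2/3 : 1/3
  set.seed(1)
  X <- allocate_reads(ds, rho, w)
  frac <- X[1, 1, 1] / 10000
  se <- sqrt(2/3 * 1/3 / 10000)
  expect_lt(abs(frac - 2/3), 3 * se)
  expect_equal(sum(X), 10000)

  # single-member EC: deterministic
  ds1 <- ec_dataset(cat0, samples, c(s1 = "A"), list(cbind(1L, 2L)),
                    matrix(9, 1, 1))
  X1 <- allocate_reads(ds1, rho, matrix(1, 2, 2))
  expect_equal(X1[1, 2, 1], 9)
  expect_equal(sum(X1), 9)

  # all-zero member probabilities is a hard error naming the EC
  expect_error(allocate_reads(ds, rho, matrix(0, 2, 2)), "EC 1")
})

test_that("rho draws follow the conjugate Dirichlet posterior", {
  set.seed(2)
  # prior-only: Dirichlet(1,1) has mean (1/2, 1/2)
  d0 <- t(replicate(4000, sample_rho(c(0, 0), 1)))
  expect_lt(max(abs(colMeans(d0) - 0.5)), 3 * 0.5 / sqrt(12 * 4000) * 2)
  # Y = (30, 10): posterior Dirichlet(31, 11), mean (31/42, 11/42)
  d1 <- t(replicate(10000, sample_rho(c(30, 10), 1)))
  m <- 31 / 42
  se <- sqrt(m * (1 - m) / 43) / sqrt(10000)
  expect_lt(abs(mean(d1[, 1]) - m), 4 * se)
  expect_true(all(abs(rowSums(d1) - 1) < 1e-10))
  expect_true(all(d1 > 0))
})

test_that("pi draws follow the conjugate beta/Dirichlet posterior", {
  set.seed(3)
  # delta = (1,1), X = (3,1): Beta(4, 2) with mean 2/3
  p <- replicate(10000, sample_pi(c(3, 1), c(1, 1))[1])
  se <- sqrt(2/3 * 1/3 / 7) / sqrt(10000)
  expect_lt(abs(mean(p) - 2/3), 4 * se)
  # prior-only Dirichlet(2,2,2): mean 1/3 each
  p3 <- t(replicate(8000, sample_pi(c(0, 0, 0), c(2, 2, 2))))
  expect_lt(max(abs(colMeans(p3) - 1/3)), 0.01)
  # delta = (1,1), X = (50,50): mean 51/102 = 1/2
  p2 <- replicate(10000, sample_pi(c(50, 50), c(1, 1))[1])
  expect_lt(abs(mean(p2) - 0.5), 4 * sqrt(0.25 / 103) / sqrt(10000))
})

test_that("delta log-posterior matches closed forms and the beta density", {
  pr <- diffreg:::default_prior()
  prior_term <- function(dplus) dnorm(log(dplus), pr$mean_log_precision,
                                      pr$sd_log_precision, log = TRUE)
  # Beta(1,1) density is 1: likelihood part is 0
  expect_equal(log_posterior_delta(c(1, 1), 0.3, pr, jacobian = FALSE),
               prior_term(2))
  # Beta(2,1) pdf is 2x, so at x = 0.5 the log-density is 0
  expect_equal(log_posterior_delta(c(2, 1), 0.5, pr, jacobian = FALSE),
               prior_term(3))
  # general agreement with dbeta across samples
  set.seed(4)
  for (r in 1:5) {
    delta <- rexp(2, 0.1) + 0.2
    x <- rbeta(4, 2, 2)
    expect_equal(
      log_posterior_delta(delta, x, pr, jacobian = FALSE) -
        prior_term(sum(delta)),
      sum(dbeta(x, delta[1], delta[2], log = TRUE)),
      tolerance = 1e-8)
  }
  # the likelihood term is a proper density: quadrature over (0,1) gives 1
  delta <- c(2.7, 1.3)
  dens <- function(x) vapply(x, function(xx)
    exp(log_posterior_delta(delta, xx, pr, jacobian = FALSE) -
          prior_term(sum(delta))), numeric(1))
  expect_equal(stats::integrate(dens, 0, 1)$value, 1, tolerance = 1e-5)
})

test_that("a proposal equal to the current state is always accepted", {
  # zero proposal scale makes every proposal the identity: ratio 1
  st <- diffreg:::amh_init(3, 2, init_sd = 0)
  x <- matrix(rnorm(6), 3, 2)
  lp_fun <- function(xm) rep(-1, nrow(xm))
  for (k in 1:20) {
    s <- diffreg:::amh_step(st, x, lp_fun(x), lp_fun)
    expect_true(all(s$accepted))                 # flat target: ratio is 1
    expect_equal(s$x, x, tolerance = 1e-4)       # up to the covariance floor
    st <- s$state
    x <- s$x
  }
})

test_that("adaptive MH recovers a known 2-d Gaussian target", {
  set.seed(5)
  mu <- c(1, -2); sdv <- c(0.5, 1.5)
  lp_fun <- function(x) -0.5 * ((x[, 1] - mu[1])^2 / sdv[1]^2 +
                                  (x[, 2] - mu[2])^2 / sdv[2]^2)
  st <- diffreg:::amh_init(1, 2)
  x <- matrix(0, 1, 2); lp <- lp_fun(x)
  draws <- matrix(NA_real_, 10000, 2)
  for (it in 1:10000) {
    if (it == 5001) st$frozen <- TRUE
    s <- diffreg:::amh_step(st, x, lp, lp_fun)
    st <- s$state; x <- s$x; lp <- s$lp
    draws[it, ] <- x
  }
  post <- draws[5001:10000, ]
  # tolerances ~4 effective MC standard errors at ESS of a few hundred
  expect_lt(abs(mean(post[, 1]) - mu[1]), 0.12)
  expect_lt(abs(mean(post[, 2]) - mu[2]), 0.3)
  expect_lt(abs(sd(post[, 1]) / sdv[1] - 1), 0.2)
  expect_lt(abs(sd(post[, 2]) / sdv[2] - 1), 0.2)
  acc <- st$accepts / st$steps
  expect_gt(acc, 0.1); expect_lt(acc, 0.6)
})

test_that("stationarity diagnostic passes iid noise and rejects trends", {
  pass <- vapply(1:50, function(s) {
    set.seed(s); heidelberger_welch(rnorm(2000))$passed
  }, logical(1))
  expect_gte(mean(pass), 0.9)
  rej <- vapply(1:50, function(s) {
    set.seed(s); !heidelberger_welch(0.01 * (1:2000) + rnorm(2000))$passed
  }, logical(1))
  expect_gte(mean(rej), 0.9)
  # degenerate constant trace passes by definition
  expect_true(heidelberger_welch(rep(3.3, 100))$passed)
  expect_error(heidelberger_welch(rnorm(20)), "too short")
})

test_that("burn-in escalation and chain-doubling restart trigger on a short chain", {
  set.seed(4)
  X <- draw_model_counts(20, 3, dplus = 30, pibar_u = rep(0.3, 20), depth = 500)
  ds <- make_single_ec_ds(X)
  # precision initialized far below its posterior: the log-posterior trace
  # trends upward over a short chain and the protocol must escalate
  prior <- structure(list(mean_log_precision = log(1e-3),
                          sd_log_precision = 6, rho_prior_conc = 1),
                     class = "eb_prior")
  gp <- run_chain(ds, mcmc_config(n_iter = 200, burn_in = 50, seed = 4),
                  prior = prior)
  expect_true(gp$hw_escalated || gp$restarted)
  expect_true(gp$restarted)          # doubling happened
  expect_gte(gp$n_iter, 400)
  expect_false(is.na(gp$converged))  # protocol reached a verdict either way
})

test_that("chains are deterministic given a seed and conserve reads", {
  set.seed(6)
  sim <- simulate_counts(sim_scenario("bulk", n_features = 15, n_dr = 3,
                                      seed = 6))
  ds <- emulate_multimapping_ecs(sim, p_multi = 0.4, seed = 6)
  dsA <- split_groups(ds)$A
  cfg <- mcmc_config(n_iter = 150, burn_in = 40, seed = 99)
  g1 <- run_chain(dsA, cfg)
  g2 <- run_chain(dsA, cfg)
  expect_identical(g1$pi_bar, g2$pi_bar)
  expect_identical(g1$lp_trace, g2$lp_trace)
  # conservation of the final latent allocation, per sample
  tot <- apply(g1$X_final, 3, sum)
  expect_equal(unname(tot), unname(total_reads(dsA)))
})

test_that("uniquely-mapping limit matches an independent MH oracle", {
  set.seed(8)
  T <- 2; N <- 3
  X <- draw_model_counts(T, N, dplus = 12, pibar_u = c(0.3, 0.6), depth = 120)
  ds <- make_single_ec_ds(X)
  prior <- structure(list(mean_log_precision = log(15), sd_log_precision = 1,
                          rho_prior_conc = 1), class = "eb_prior")
  gp <- run_chain(ds, mcmc_config(n_iter = 6000, burn_in = 1000, seed = 8,
                                  store_pi = TRUE), prior = prior)
  keep <- (gp$burn_in + 1):gp$n_iter

  # oracle: random-walk MH on (logit pi_1..pi_N, log deltaS, log deltaU),
  # a different parameterization than the sampler's, targeting the exact
  # per-feature posterior p(pi, delta | X) of the no-multimapping model
  oracle <- function(xs, xu, n_iter = 60000) {
    lt <- function(th) {
      p <- plogis(th[1:N]); a <- exp(th[N + 1]); b <- exp(th[N + 2])
      dp <- a + b
      sum(xs * log(p) + xu * log(1 - p)) +
        sum(dbeta(p, a, b, log = TRUE)) +
        sum(log(p) + log(1 - p)) +                       # logit Jacobian
        dnorm(log(dp), prior$mean_log_precision,
              prior$sd_log_precision, log = TRUE) +
        log(a) + log(b) - 2 * log(dp)                    # prior + Jacobian
    }
    th <- c(qlogis(pmin(pmax(xs / (xs + xu), 0.05), 0.95)), log(8), log(8))
    cur <- lt(th)
    out <- matrix(NA_real_, n_iter, N + 2)
    step <- c(rep(0.15, N), 0.4, 0.4)
    for (it in 1:n_iter) {
      prop <- th + rnorm(N + 2) * step
      lp <- lt(prop)
      if (is.finite(lp) && log(runif(1)) < lp - cur) { th <- prop; cur <- lp }
      out[it, ] <- th
    }
    out[seq(10001, n_iter, by = 5), ]
  }
  for (t in 1:T) {
    o <- oracle(X[t, 1, ], X[t, 2, ])
    # spliced proportion of sample 1 (oracle) vs stored pi chain
    pi_o <- plogis(o[, 1])
    pi_c <- gp$pi[keep, t, 1, 1]
    expect_lt(abs(mean(pi_o) - mean(pi_c)), 0.03)
    expect_lt(abs(sd(pi_o) - sd(pi_c)), 0.02)
    # group-level unspliced proportion pi_bar_U
    pb_o <- exp(o[, N + 2]) / (exp(o[, N + 1]) + exp(o[, N + 2]))
    pb_c <- gp$pi_bar[keep, t, 2]
    expect_lt(abs(mean(pb_o) - mean(pb_c)), 0.04)
    expect_lt(abs(quantile(pb_o, 0.25) - quantile(pb_c, 0.25)), 0.05)
    expect_lt(abs(quantile(pb_o, 0.75) - quantile(pb_c, 0.75)), 0.05)
  }
})

test_that("duplicate features with symmetric ECs are statistically identical", {
  set.seed(10)
  T <- 2; N <- 4
  X <- array(0, dim = c(T, 2, N))
  for (i in 1:N) {
    y <- 400; xu <- rbinom(1, y, 0.35)
    X[1, , i] <- c(y - xu, xu)
    X[2, , i] <- X[1, , i]        # exact duplicate
  }
  ds <- make_single_ec_ds(X)
  gp <- run_chain(ds, mcmc_config(n_iter = 1500, burn_in = 400, seed = 10))
  u <- pi_tilde_u(gp)
  expect_lt(abs(mean(u[, 1]) - mean(u[, 2])), 0.02)
  expect_lt(abs(sd(u[, 1]) - sd(u[, 2])), 0.02)
})

test_that("stored chains are valid simplices with positive precision", {
  set.seed(12)
  sim <- simulate_counts(sim_scenario("bulk", n_features = 10, n_dr = 2,
                                      seed = 12))
  ds <- emulate_multimapping_ecs(sim, p_multi = 0.3, seed = 12)
  gp <- run_chain(split_groups(ds)$B, mcmc_config(n_iter = 120, burn_in = 30,
                                                  seed = 12))
  expect_true(all(abs(apply(gp$pi_bar, c(1, 2), sum) - 1) < 1e-8))
  expect_true(all(gp$pi_bar > 0))
  expect_true(all(gp$delta_plus > 0))
})
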