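#' Fit the differential-regulation model on a two-group EC dataset
#'
#' The main fitting function.  Applies the minimum-count filter, estimates the
#' empirical-Bayes prior on the pooled data, runs the data-augmentation MCMC
#' independently in each group (bulk or single-cell model according to the
#' catalog mode), and compares the groups through the posterior probability of
#' up-regulation and the Wald test.
#'
#' @param ds an [ec_dataset()] with exactly two groups assigned.
#' @param config an [mcmc_config()]; set `config$seed` for reproducibility.
#' @param min_count per-group minimum EC-compatible count a feature needs to
#'   be analyzed (default 10); `0` disables filtering.
#' @param prior optional `eb_prior`, estimated from the pooled filtered data
#'   when `NULL`.
#' @param all_pairs use the all-pairs estimator of the up-regulation
#'   probability.
#' @return an object of class `diffreg_fit` with components `results` (the
#'   per-feature table), `posteriors` (the two `group_posterior`s), `prior`,
#'   `groups` and `catalog`.  Use `summary()` for the ranked table, `coef()`
#'   for posterior means and `plot()` for traceplots.
#' @examples
#' sc <- sim_scenario(mode = "bulk", n_features = 40, n_dr = 8,
#'                    n_samples_per_group = 3, seed = 1)
#' sim <- simulate_counts(sc)
#' ds <- emulate_multimapping_ecs(sim, p_multi = 0.2)
#' fit <- diffreg(ds, mcmc_config(n_iter = 300, burn_in = 100, seed = 1))
#' head(summary(fit))
#' @export
diffreg <- function(ds, config = mcmc_config(), min_count = 10, prior = NULL,
                    all_pairs = FALSE) {
  stopifnot(inherits(ds, "ec_dataset"))
  groups <- sort(unique(as.character(stats::na.omit(ds$group_of))))
  if (length(groups) != 2)
    stop("differential testing needs exactly two groups, found ",
         length(groups))
  if (min_count > 0) ds <- filter_min_counts(ds, min_count)
  if (length(ds$catalog$feature_ids) == 0)
    stop("no features pass the minimum-count filter")
  gs <- split_groups(ds)
  fits <- fit_bulk(gs[[1]], gs[[2]], config = config, prior = prior)
  gp_a <- fits[[groups[1]]]; gp_b <- fits[[groups[2]]]
  results <- test_differential(gp_a, gp_b, all_pairs = all_pairs)
  structure(list(results = results,
                 posteriors = setNames(list(gp_a, gp_b), groups),
                 prior = fits$prior, groups = groups,
                 catalog = ds$catalog, config = config,
                 mode = ds$catalog$mode),
            class = "diffreg_fit")
}

#' @export
print.diffreg_fit <- function(x, ...) {
  cat("<diffreg_fit> ", x$mode, " model: ", nrow(x$results),
      " features, groups ", x$groups[1], " vs ", x$groups[2], "\n", sep = "")
  conv <- x$results$converged[1]
  cat("  chains: ", x$posteriors[[1]]$n_iter, " iterations (burn-in ",
      x$posteriors[[1]]$burn_in, "); converged: ", format(conv), "\n", sep = "")
  top <- head(rank_results(x$results), 5)
  cat("  top features by max(p, 1-p):\n")
  print(top[, c("rank", "feature_id", "p", "wald_pvalue",
                "mean_piU_A", "mean_piU_B")], digits = 3)
  invisible(x)
}

#' Ranked result table of a fitted model
#'
#' @param object a `diffreg_fit`.
#' @param by ranking mode, `"probability"` (default) or `"wald"`.
#' @param ... unused.
#' @return the ranked per-feature result `data.frame`.
#' @export
summary.diffreg_fit <- function(object, by = "probability", ...) {
  rank_results(object$results, by = by)
}

#' Posterior means of the comparison parameter
#'
#' @param object a `diffreg_fit`.
#' @param ... unused.
#' @return matrix features x groups of posterior mean `pi_tilde_U`.
#' @export
coef.diffreg_fit <- function(object, ...) {
  out <- cbind(object$results$mean_piU_A, object$results$mean_piU_B)
  dimnames(out) <- list(object$results$feature_id, object$groups)
  out
}

#' Results accessor
#'
#' @param fit a `diffreg_fit` or `diffreg_sc_fit`.
#' @return the per-feature result table (with a `cluster_id` column for
#'   single-cell fits).
#' @export
results <- function(fit) {
  if (inherits(fit, "diffreg_fit")) return(fit$results)
  if (inherits(fit, "diffreg_sc_fit")) {
    do.call(rbind, lapply(names(fit$clusters), function(cl) {
      r <- fit$clusters[[cl]]$results
      cbind(cluster_id = cl, r, stringsAsFactors = FALSE)
    }))
  } else stop("not a fitted diffreg object")
}

## ---------------------------------------------------------------------------
## single-cell pipeline
## ---------------------------------------------------------------------------

#' Comparison parameter of the single-cell model
#'
#' `pi_tilde_U = pi_bar_U + 0.5 * pi_bar_A`: half of the ambiguous mass is
#' attributed to the unspliced version.  Ambiguous reads are never
#' re-allocated between S and U at the read level — they enter the
#' Dirichlet-multinomial as their own category — so this split only happens
#' at the comparison stage.
#'
#' @param pi_bar_u,pi_bar_a chains (or scalars) of the group-level unspliced
#'   and ambiguous proportions.
#' @return values in `[0, 1]`.
#' @export
pi_tilde_sc <- function(pi_bar_u, pi_bar_a) {
  out <- pi_bar_u + 0.5 * pi_bar_a
  stopifnot(all(out >= 0 & out <= 1 + 1e-12))
  pmin(out, 1)
}

#' Per-cluster differential regulation from single-cell counts
#'
#' For each cell cluster: pseudo-bulk aggregation of the spliced / unspliced /
#' ambiguous counts per sample, minimum-count filtering, and an independent
#' two-group fit with the single-cell (Dirichlet-multinomial) model — no
#' effective-length normalization, ambiguous reads as their own category.
#' Multi-gene equivalence classes, when available at the pseudo-bulk level,
#' drive the latent allocation.  Cluster seeds are derived from the master
#' seed and the cluster identifier, so results do not depend on the order in
#' which clusters are processed.  Clusters failing their preconditions (fewer
#' than 2 samples per group, nothing left after filtering) are skipped with a
#' warning.
#'
#' @param cell_counts list with genes x cells matrices `S`, `U`, `A`.
#' @param assign data frame `cell_id`, `sample_id`, `cluster_id`.
#' @param groups named vector `sample_id -> group label` (two labels).
#' @param config an [mcmc_config()].
#' @param ecs optional named list, per cluster, of pseudo-bulk
#'   [ec_dataset()]s carrying multi-gene ECs.
#' @param min_count per-group minimum count (default 10).
#' @return an object of class `diffreg_sc_fit`: per-cluster `diffreg_fit`s.
#' @export
fit_sc <- function(cell_counts, assign, groups, config = mcmc_config(),
                   ecs = NULL, min_count = 10) {
  clusters <- sort(unique(assign$cluster_id))
  seed <- config$seed %||% sample.int(2147483600L, 1)
  fits <- list()
  for (cl in clusters) {
    ds <- tryCatch({
      if (!is.null(ecs) && !is.null(ecs[[cl]])) {
        set_groups(ecs[[cl]], groups)
      } else {
        aggregate_pseudobulk(cell_counts, assign, cl, groups = groups)
      }
    }, error = function(e) e)
    if (inherits(ds, "error")) {
      warning("cluster '", cl, "' skipped: ", conditionMessage(ds))
      next
    }
    per_group <- table(ds$group_of)
    if (length(per_group) < 2 || any(per_group < 2)) {
      warning("cluster '", cl, "' skipped: fewer than 2 samples per group")
      next
    }
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("cluster-", cl))
    fit <- tryCatch(diffreg(ds, cfg, min_count = min_count),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("cluster '", cl, "' skipped: ", conditionMessage(fit))
      next
    }
    fits[[cl]] <- fit
  }
  structure(list(clusters = fits, seed = seed, config = config),
            class = "diffreg_sc_fit")
}

#' @export
print.diffreg_sc_fit <- function(x, ...) {
  cat("<diffreg_sc_fit> ", length(x$clusters), " analyzed clusters\n", sep = "")
  for (cl in names(x$clusters))
    cat("  ", cl, ": ", nrow(x$clusters[[cl]]$results), " genes\n", sep = "")
  invisible(x)
}
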