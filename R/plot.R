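#' Traceplot and posterior density of the comparison parameter
#'
#' Visual convergence/mixing check for one feature: the post-burn-in chains
#' of the unspliced comparison parameter in both groups (left panel) and
#' their marginal posterior densities (right panel).
#'
#' @param fit a `diffreg_fit`.
#' @param feature feature identifier.
#' @param file optional output path ending in `.png` or `.pdf`; when `NULL`
#'   the current graphics device is used.
#' @return invisibly, the file path (or `NULL`).
#' @export
plot_traceplot <- function(fit, feature, file = NULL) {
  stopifnot(inherits(fit, "diffreg_fit"))
  ids <- fit$catalog$feature_ids
  if (!feature %in% ids) {
    near <- agrep(feature, ids, max.distance = 0.3, value = TRUE)
    stop("feature '", feature, "' not found",
         if (length(near)) paste0("; near matches: ",
                                  paste(head(near, 5), collapse = ", ")))
  }
  t <- match(feature, ids)
  ua <- pi_tilde_u(fit$posteriors[[1]])[, t]
  ub <- pi_tilde_u(fit$posteriors[[2]])[, t]
  cols <- c("#1f77b4", "#d62728")

  if (!is.null(file)) {
    if (endsWith(file, ".pdf")) grDevices::pdf(file, width = 9, height = 4)
    else grDevices::png(file, width = 900, height = 400)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  ylim <- range(ua, ub)
  if (diff(ylim) == 0) ylim <- ylim + c(-0.01, 0.01)
  graphics::plot(ua, type = "l", col = cols[1], ylim = ylim,
                 xlab = "iteration (post burn-in)",
                 ylab = expression(tilde(pi)[U]),
                 main = paste0(feature, ": trace"))
  graphics::lines(ub, col = cols[2])
  graphics::legend("topright", legend = fit$groups, col = cols, lty = 1,
                   bty = "n")
  dens <- lapply(list(ua, ub), function(x)
    if (sd(x) > 1e-12) density(x) else NULL)
  xs <- unlist(lapply(dens, `[[`, "x")); ys <- unlist(lapply(dens, `[[`, "y"))
  graphics::plot(NA, xlim = range(xs, ua, ub) + c(-0.02, 0.02),
                 ylim = c(0, max(ys, 1)),
                 xlab = expression(tilde(pi)[U]), ylab = "density",
                 main = paste0(feature, ": posterior density"))
  for (k in 1:2) {
    if (is.null(dens[[k]])) graphics::abline(v = list(ua, ub)[[k]][1],
                                             col = cols[k])
    else graphics::lines(dens[[k]], col = cols[k])
  }
  invisible(file)
}

#' @param x a `diffreg_fit`.
#' @param feature feature to plot (default: top-ranked feature).
#' @param ... unused.
#' @rdname plot_traceplot
#' @export
plot.diffreg_fit <- function(x, feature = NULL, ...) {
  if (is.null(feature))
    feature <- rank_results(x$results)$feature_id[1]
  plot_traceplot(x, feature)
}
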