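## ---------------------------------------------------------------------------
## Synthetic benchmark generator.
##
## Count-level simulation of the study scenarios (differential regulation,
## differential gene expression, differential alternative splicing, null,
## batch, single-cell sparsity), followed by an equivalence-class emulator
## that introduces multi-mapping ambiguity while conserving reads exactly.
## Ground truth is recorded per feature for ROC / false-discovery scoring.
## ---------------------------------------------------------------------------

#' Simulation scenario
#'
#' Collects every knob of the generator.  Defaults reproduce the benchmark
#' conditions: bulk — 6 samples in two groups of 3, 2,000 differentially
#' regulated (DR) transcripts whose spliced/unspliced proportions are inverted
#' in one randomly chosen group; single-cell — 20% DR genes per cell cluster
#' (distinct genes per cluster), 90% zero cells.  Differential gene expression
#' (DGE) multiplies one group's mean by `1 + Exponential(mean_fc - 1)`, so
#' fold changes average `mean_fc` (3, 6 or 9); differential alternative
#' splicing (DAS, bulk only) cyclically permutes transcript abundances within
#' multi-transcript genes, preserving gene totals and per-transcript
#' unspliced proportions.  DGE and DAS are nuisance effects: they must not be
#' flagged as DR.
#'
#' @param mode `"bulk"` or `"sc"`.
#' @param n_features number of transcripts (bulk, default 10000) or genes per
#'   cluster (sc, default 2000).
#' @param n_samples_per_group samples per condition (bulk default 3, sc 2).
#' @param n_dr number of DR features (bulk default 2000).
#' @param dr_fraction fraction of DR features (sc default 0.2; overrides
#'   `n_dr` when set).
#' @param mean_fc average DGE fold change (3, 6 or 9); `NULL` disables DGE.
#' @param dge_fraction fraction of features with DGE (default 0.1).
#' @param das simulate DAS (bulk only).
#' @param das_fraction fraction of multi-transcript genes with DAS.
#' @param batch add a balanced 2-batch design (see [apply_batch_design()]).
#' @param zero_fraction fraction of zero-expression cells (sc; 0.90, 0.95 or
#'   0.99).
#' @param n_clusters number of cell clusters (sc, default 3).
#' @param n_cells cells per sample per cluster (sc, default 200).
#' @param depth mean reads per feature per sample (default 200).
#' @param abund_sdlog log-sd of the baseline relative abundances.
#' @param disp_meanlog,disp_sdlog log-normal negative-binomial dispersion
#'   across features (biological replicate variability).
#' @param prec_meanlog,prec_sdlog log-normal precision `delta+` of the
#'   splice-proportion hierarchy across features.
#' @param pi_u optional fixed baseline unspliced proportion (scalar or per
#'   feature); drawn from `Beta(pi_u_shape)` when `NULL`.
#' @param pi_u_shape beta shape parameters of the baseline unspliced
#'   proportion (default `c(2, 6)`, mean 0.25).
#' @param pi_a_shape beta shape of the ambiguous read fraction (sc only).
#' @param seed integer seed.
#' @return a list of class `sim_scenario`.
#' @export
sim_scenario <- function(mode = c("bulk", "sc"), n_features = NULL,
                         n_samples_per_group = NULL, n_dr = NULL,
                         dr_fraction = NULL, mean_fc = NULL,
                         dge_fraction = 0.1, das = FALSE, das_fraction = 0.1,
                         batch = FALSE, zero_fraction = 0.90, n_clusters = 3,
                         n_cells = 200, depth = 200, abund_sdlog = 1,
                         disp_meanlog = -2, disp_sdlog = 0.5,
                         prec_meanlog = log(30), prec_sdlog = 0.5,
                         pi_u = NULL, pi_u_shape = c(2, 6),
                         pi_a_shape = c(2, 18), seed = 1) {
  mode <- match.arg(mode)
  n_features <- n_features %||% if (mode == "bulk") 10000L else 2000L
  n_samples_per_group <- n_samples_per_group %||% if (mode == "bulk") 3L else 2L
  if (mode == "bulk") {
    if (is.null(dr_fraction) && is.null(n_dr)) n_dr <- 2000L
    if (!is.null(dr_fraction)) n_dr <- round(dr_fraction * n_features)
  } else {
    dr_fraction <- dr_fraction %||% 0.2
    n_dr <- round(dr_fraction * n_features)
  }
  if (n_dr > n_features) stop("n_dr exceeds n_features")
  if (!is.null(mean_fc) && mean_fc <= 1) stop("mean_fc must be > 1")
  stopifnot(zero_fraction >= 0, zero_fraction < 1,
            dge_fraction >= 0, dge_fraction <= 1)
  if (mode == "sc" && n_dr * n_clusters > n_features)
    stop("cannot pick distinct DR genes per cluster: dr_fraction * n_clusters > 1")
  structure(as.list(environment()), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$mode, ": ", x$n_features, " features, ",
      x$n_samples_per_group, "+", x$n_samples_per_group, " samples, ",
      x$n_dr, " DR",
      if (!is.null(x$mean_fc)) paste0(", DGE mean FC ", x$mean_fc),
      if (x$das) ", DAS", if (x$batch) ", 2 batches",
      if (x$mode == "sc") paste0(", ", x$n_clusters, " clusters, zero fraction ",
                                 x$zero_fraction), "\n", sep = "")
  invisible(x)
}

## draw per-sample counts for one condition layout:
## mu T-vector of expected totals, piu group-level unspliced proportion,
## returns T x V matrix per sample
draw_sample_counts <- function(mu, disp, prec, pi_group) {
  T <- length(mu); V <- ncol(pi_group)
  y <- rnbinom(T, mu = mu, size = 1 / disp)
  alpha <- prec * pi_group
  p <- matrix(0, T, V)
  for (v in seq_len(V)) p[, v] <- rgamma(T, shape = pmax(alpha[, v], 1e-8))
  p <- pmax(p, 1e-300); p <- p / rowSums(p)
  X <- matrix(0L, T, V)
  rem <- y; acc <- rep(0, T)
  for (v in seq_len(V - 1)) {
    cond <- pmin(pmax(p[, v] / pmax(1 - acc, 1e-12), 0), 1)
    X[, v] <- rbinom(T, rem, cond)
    rem <- rem - X[, v]
    acc <- acc + p[, v]
  }
  X[, V] <- rem
  X
}

#' Simulate ground-truth counts for a scenario
#'
#' Draws baseline relative abundances (log-normal), per-feature dispersions
#' and splice-proportion precisions, applies the configured DR / DGE / DAS
#' effects to one randomly chosen group per affected feature, and generates
#' per-sample counts: negative-binomial totals, then a hierarchical
#' beta(-binomial) (bulk) or Dirichlet(-multinomial) (single-cell) split into
#' splice versions.  DR features have their spliced and unspliced proportions
#' swapped in the affected group; all other generating parameters are
#' identical across groups.  In single-cell mode the per-sample gene totals
#' are additionally spread over cells at the configured zero fraction,
#' keeping totals fixed.
#'
#' @param scenario a [sim_scenario()].
#' @return an object of class `sim_counts`: per-sample count matrices
#'   (features x versions), the `truth` data frame, group labels, effective
#'   lengths (bulk) and — in sc mode — sparse cell-level matrices with a
#'   cell assignment table.
#' @export
simulate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  if (scenario$mode == "bulk") simulate_counts_bulk(scenario)
  else simulate_counts_sc(scenario)
}

simulate_counts_bulk <- function(sc) {
  T <- sc$n_features; n <- sc$n_samples_per_group
  samples <- paste0("s", seq_len(2 * n))
  group_of <- setNames(rep(c("A", "B"), each = n), samples)
  feature_ids <- sprintf("t%05d", seq_len(T))

  ## gene structure (1-3 transcripts per gene), needed for DAS
  sizes <- sample(1:3, T, replace = TRUE)
  sizes <- sizes[cumsum(sizes) <= T]
  if (sum(sizes) < T) sizes <- c(sizes, T - sum(sizes))
  gene_of <- rep(seq_along(sizes), sizes)

  rel <- rlnorm(T, 0, sc$abund_sdlog); rel <- rel / sum(rel)
  disp <- rlnorm(T, sc$disp_meanlog, sc$disp_sdlog)
  prec <- rlnorm(T, sc$prec_meanlog, sc$prec_sdlog)
  piu0 <- if (!is.null(sc$pi_u)) rep_len(sc$pi_u, T)
  else rbeta(T, sc$pi_u_shape[1], sc$pi_u_shape[2])

  truth <- data.frame(feature_id = feature_ids, gene_id = paste0("g", gene_of),
                      is_dr = FALSE, is_dge = FALSE, is_das = FALSE,
                      affected_group = NA_character_,
                      pi_u_A = piu0, pi_u_B = piu0,
                      fold_change = NA_real_, stringsAsFactors = FALSE)

  ## DR: invert s/u proportions in one randomly chosen group
  if (sc$n_dr > 0) {
    dr <- sample.int(T, sc$n_dr)
    aff <- sample(c("A", "B"), sc$n_dr, replace = TRUE)
    truth$is_dr[dr] <- TRUE
    truth$affected_group[dr] <- aff
    truth$pi_u_A[dr[aff == "A"]] <- 1 - piu0[dr[aff == "A"]]
    truth$pi_u_B[dr[aff == "B"]] <- 1 - piu0[dr[aff == "B"]]
  }

  ## DGE: multiply one group's mean; fold change 1 + Exp(mean_fc - 1)
  fc_mult <- matrix(1, T, 2, dimnames = list(NULL, c("A", "B")))
  if (!is.null(sc$mean_fc)) {
    n_dge <- round(sc$dge_fraction * T)
    dge <- sample.int(T, n_dge)
    fc <- 1 + rexp(n_dge, rate = 1 / (sc$mean_fc - 1))
    aff <- sample(c("A", "B"), n_dge, replace = TRUE)
    truth$is_dge[dge] <- TRUE
    truth$fold_change[dge] <- fc
    truth$affected_group[dge] <- ifelse(is.na(truth$affected_group[dge]),
                                        aff, truth$affected_group[dge])
    fc_mult[cbind(dge, match(aff, c("A", "B")))] <- fc
  }

  ## DAS: cyclic permutation of within-gene transcript abundances in one group
  rel_group <- cbind(A = rel, B = rel)
  if (isTRUE(sc$das)) {
    multi_genes <- unique(gene_of[duplicated(gene_of)])
    n_das <- round(sc$das_fraction * length(multi_genes))
    das_genes <- sample(multi_genes, n_das)
    aff <- sample(c("A", "B"), n_das, replace = TRUE)
    for (j in seq_along(das_genes)) {
      idx <- which(gene_of == das_genes[j])
      rel_group[idx, aff[j]] <- rel_group[c(idx[-1], idx[1]), aff[j]]
      truth$is_das[idx] <- TRUE
      truth$affected_group[idx] <- ifelse(is.na(truth$affected_group[idx]),
                                          aff[j], truth$affected_group[idx])
    }
  }

  mu <- list(A = T * sc$depth * rel_group[, "A"] * fc_mult[, "A"],
             B = T * sc$depth * rel_group[, "B"] * fc_mult[, "B"])
  pig <- list(A = cbind(S = 1 - truth$pi_u_A, U = truth$pi_u_A),
              B = cbind(S = 1 - truth$pi_u_B, U = truth$pi_u_B))
  counts <- lapply(samples, function(s) {
    g <- group_of[s]
    X <- draw_sample_counts(mu[[g]], disp, prec, pig[[g]])
    dimnames(X) <- list(feature_ids, c("S", "U"))
    X
  })
  names(counts) <- samples

  eff_len_S <- rlnorm(T, log(1500), 0.4)
  eff_len_U <- eff_len_S * runif(T, 1.5, 3)

  structure(list(mode = "bulk", feature_ids = feature_ids,
                 versions = c("S", "U"), samples = samples,
                 group_of = group_of, counts = counts, truth = truth,
                 eff_len_S = eff_len_S, eff_len_U = eff_len_U,
                 scenario = sc),
            class = "sim_counts")
}

simulate_counts_sc <- function(sc) {
  G <- sc$n_features; n <- sc$n_samples_per_group
  samples <- paste0("s", seq_len(2 * n))
  group_of <- setNames(rep(c("A", "B"), each = n), samples)
  feature_ids <- sprintf("g%05d", seq_len(G))
  clusters <- paste0("cl", seq_len(sc$n_clusters))

  ## distinct DR genes per cluster
  perm <- sample.int(G)
  dr_sets <- split(perm[seq_len(sc$n_dr * sc$n_clusters)],
                   rep(seq_len(sc$n_clusters), each = sc$n_dr))

  cluster_data <- list(); truth_all <- NULL
  assign_all <- NULL
  cellsS <- list(); cellsU <- list(); cellsA <- list()
  for (ci in seq_along(clusters)) {
    rel <- rlnorm(G, 0, sc$abund_sdlog); rel <- rel / sum(rel)
    disp <- rlnorm(G, sc$disp_meanlog, sc$disp_sdlog)
    prec <- rlnorm(G, sc$prec_meanlog, sc$prec_sdlog)
    pia <- rbeta(G, sc$pi_a_shape[1], sc$pi_a_shape[2])
    piu_frac <- if (!is.null(sc$pi_u)) rep_len(sc$pi_u, G)
    else rbeta(G, sc$pi_u_shape[1], sc$pi_u_shape[2])
    piS0 <- (1 - piu_frac) * (1 - pia)
    piU0 <- piu_frac * (1 - pia)

    truth <- data.frame(cluster_id = clusters[ci], feature_id = feature_ids,
                        is_dr = FALSE, is_dge = FALSE,
                        affected_group = NA_character_,
                        pi_u_A = piU0, pi_u_B = piU0, pi_a = pia,
                        fold_change = NA_real_, stringsAsFactors = FALSE)
    pig <- list(A = cbind(S = piS0, U = piU0, A = pia),
                B = cbind(S = piS0, U = piU0, A = pia))
    dr <- dr_sets[[ci]]
    aff <- sample(c("A", "B"), length(dr), replace = TRUE)
    truth$is_dr[dr] <- TRUE
    truth$affected_group[dr] <- aff
    for (g in c("A", "B")) {
      sw <- dr[aff == g]
      pig[[g]][sw, c("S", "U")] <- pig[[g]][sw, c("U", "S")]
      col <- paste0("pi_u_", g)
      truth[[col]][sw] <- piS0[sw]
    }

    fc_mult <- matrix(1, G, 2, dimnames = list(NULL, c("A", "B")))
    if (!is.null(sc$mean_fc)) {
      n_dge <- round(sc$dge_fraction * G)
      dge <- sample.int(G, n_dge)
      fc <- 1 + rexp(n_dge, rate = 1 / (sc$mean_fc - 1))
      aff2 <- sample(c("A", "B"), n_dge, replace = TRUE)
      truth$is_dge[dge] <- TRUE
      truth$fold_change[dge] <- fc
      fc_mult[cbind(dge, match(aff2, c("A", "B")))] <- fc
    }

    counts <- lapply(samples, function(s) {
      g <- group_of[s]
      X <- draw_sample_counts(G * sc$depth * rel * fc_mult[, g], disp, prec,
                              pig[[g]])
      dimnames(X) <- list(feature_ids, c("S", "U", "A"))
      X
    })
    names(counts) <- samples

    ## spread pseudo-bulk totals over cells at the requested zero fraction
    spread <- spread_to_cells(counts, clusters[ci], sc$n_cells,
                              sc$zero_fraction)
    cellsS[[ci]] <- spread$S; cellsU[[ci]] <- spread$U; cellsA[[ci]] <- spread$A
    assign_all <- rbind(assign_all, spread$assign)
    cluster_data[[clusters[ci]]] <- list(counts = counts)
    truth_all <- rbind(truth_all, truth)
  }

  structure(list(mode = "sc", feature_ids = feature_ids,
                 versions = c("S", "U", "A"), samples = samples,
                 group_of = group_of, clusters = cluster_data,
                 cells = list(S = do.call(cbind, cellsS),
                              U = do.call(cbind, cellsU),
                              A = do.call(cbind, cellsA)),
                 assign = assign_all, truth = truth_all, scenario = sc),
            class = "sim_counts")
}

## multinomial spread of each gene's per-sample total over its non-zero cells
spread_to_cells <- function(counts, cluster, n_cells, zero_fraction) {
  G <- nrow(counts[[1]]); samples <- names(counts)
  n_nz <- max(1L, round((1 - zero_fraction) * n_cells))
  S <- list(); U <- list(); A <- list(); assign <- NULL
  for (s in samples) {
    cell_ids <- sprintf("%s_%s_c%03d", s, cluster, seq_len(n_cells))
    assign <- rbind(assign, data.frame(cell_id = cell_ids, sample_id = s,
                                       cluster_id = cluster,
                                       stringsAsFactors = FALSE))
    ## one non-zero cell set per gene, shared by all splice versions: a cell
    ## either contains the gene's transcripts or it does not
    cell_sets <- lapply(seq_len(G), function(g) sample.int(n_cells, n_nz))
    mk <- function(v) {
      x <- counts[[s]][, v]
      i <- integer(0); j <- integer(0); val <- integer(0)
      nz <- which(x > 0)
      for (g in nz) {
        cnt <- drop(rmultinom(1, x[g], rep(1, n_nz)))
        keep <- cnt > 0
        i <- c(i, rep(g, sum(keep))); j <- c(j, cell_sets[[g]][keep])
        val <- c(val, cnt[keep])
      }
      Matrix::sparseMatrix(i = i, j = j, x = val, dims = c(G, n_cells),
                           dimnames = list(rownames(counts[[s]]), cell_ids))
    }
    S[[s]] <- mk("S"); U[[s]] <- mk("U"); A[[s]] <- mk("A")
  }
  list(S = do.call(cbind, S), U = do.call(cbind, U), A = do.call(cbind, A),
       assign = assign)
}

#' @export
print.sim_counts <- function(x, ...) {
  cat("<sim_counts> ", x$mode, ": ", length(x$feature_ids), " features, ",
      length(x$samples), " samples; DR features: ", sum(x$truth$is_dr),
      "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## equivalence-class emulation
## ---------------------------------------------------------------------------

#' Emulate multi-mapping equivalence classes from true counts
#'
#' Replaces a read-level simulation: each (feature, version)'s reads are
#' split, per sample, into a uniquely-mapping part (probability
#' `1 - p_multi` per read) emitted as a single-member EC, and a
#' multi-mapping part assigned to an EC joining 2..`max_members` randomly
#' chosen (feature, version) partners — including, when allowed, the other
#' splice version of the same feature.  EC member sets are shared across
#' samples, duplicate sets are merged, and total reads are conserved exactly.
#'
#' @param sim a `sim_counts` object (bulk), or a plain list of per-sample
#'   `T x V` count matrices for one cluster of an sc simulation.
#' @param p_multi per-read probability of multi-mapping (default 0.3).
#' @param max_members maximal EC size (default 4).
#' @param within_gene_su_overlap may an EC join the two splice versions of
#'   the same feature?
#' @param cluster for sc simulations: which cluster to emulate.
#' @param seed optional seed (defaults to continuing the current RNG stream).
#' @return an [ec_dataset()] (bulk-transcript or sc-gene mode).
#' @export
emulate_multimapping_ecs <- function(sim, p_multi = 0.3, max_members = 4,
                                     within_gene_su_overlap = TRUE,
                                     cluster = NULL, seed = NULL) {
  stopifnot(p_multi >= 0, p_multi <= 1, max_members >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(sim, "sim_counts") && sim$mode == "sc") {
    if (is.null(cluster)) stop("specify which cluster to emulate")
    counts <- sim$clusters[[cluster]]$counts
  } else if (inherits(sim, "sim_counts")) {
    counts <- sim$counts
  } else {
    counts <- sim$counts %||% sim
  }
  T <- nrow(counts[[1]]); V <- ncol(counts[[1]]); N <- length(counts)
  samples <- names(counts)
  mode <- if (V == 2) "bulk-transcript" else "sc-gene"
  catalog <- if (inherits(sim, "sim_counts") && sim$mode == "bulk")
    feature_catalog(sim$feature_ids, mode, sim$eff_len_S, sim$eff_len_U)
  else feature_catalog(rownames(counts[[1]]) %||% sprintf("f%05d", seq_len(T)),
                       mode)

  ## per (feature, version): binomial split into unique vs multi reads
  C <- array(0, dim = c(T, V, N))
  for (i in seq_len(N)) C[, , i] <- counts[[i]]
  M <- array(rbinom(T * V * N, as.vector(C), p_multi), dim = dim(C))
  Uq <- C - M

  members <- list(); cnt <- list()
  ## unique single-member ECs
  for (v in seq_len(V)) {
    tot <- matrix(Uq[, v, ], T, N)
    nz <- which(rowSums(tot) > 0)
    for (f in nz) {
      members[[length(members) + 1]] <- cbind(f, v)
      cnt[[length(cnt) + 1]] <- tot[f, ]
    }
  }
  ## multi-member EC template per (feature, version) with multi reads
  nfv <- T * V
  for (v in seq_len(V)) {
    tot <- matrix(M[, v, ], T, N)
    nz <- which(rowSums(tot) > 0)
    for (f in nz) {
      k <- if (max_members == 2) 2L else sample(2:max_members, 1)
      self <- f + T * (v - 1L)
      partners <- integer(0)
      guard <- 0
      while (length(partners) < k - 1 && guard < 50) {
        cand <- sample.int(nfv, k - 1 - length(partners))
        cand <- setdiff(cand, c(self, partners))
        if (!within_gene_su_overlap)
          cand <- cand[((cand - 1L) %% T) + 1L != f]
        partners <- c(partners, cand)
        guard <- guard + 1
      }
      fv <- c(self, partners)
      members[[length(members) + 1]] <-
        cbind(((fv - 1L) %% T) + 1L, ((fv - 1L) %/% T) + 1L)
      cnt[[length(cnt) + 1]] <- tot[f, ]
    }
  }
  counts_mat <- do.call(rbind, cnt)
  if (is.null(counts_mat)) counts_mat <- matrix(0, 0, N)
  colnames(counts_mat) <- samples
  m <- merge_duplicate_ecs(members, counts_mat)
  group_of <- if (inherits(sim, "sim_counts")) sim$group_of[samples]
  else setNames(rep(NA_character_, N), samples)
  ec_dataset(catalog, samples, group_of, m$members, m$counts)
}

#' One-call simulation of an analyzable dataset
#'
#' Runs [simulate_counts()] and [emulate_multimapping_ecs()] back to back.
#'
#' @param scenario a [sim_scenario()].
#' @param p_multi,max_members,within_gene_su_overlap passed to the emulator.
#' @return list with `ds` (an [ec_dataset()]; for sc scenarios a named list
#'   of per-cluster datasets), `truth`, and the `sim_counts` object.
#' @export
simulate_dataset <- function(scenario, p_multi = 0.3, max_members = 4,
                             within_gene_su_overlap = TRUE) {
  sim <- simulate_counts(scenario)
  if (sim$mode == "bulk") {
    ds <- emulate_multimapping_ecs(sim, p_multi, max_members,
                                   within_gene_su_overlap)
  } else {
    ds <- lapply(names(sim$clusters), function(cl)
      emulate_multimapping_ecs(sim, p_multi, max_members,
                               within_gene_su_overlap, cluster = cl))
    names(ds) <- names(sim$clusters)
  }
  list(ds = ds, truth = sim$truth, sim = sim)
}

## ---------------------------------------------------------------------------
## batch design
## ---------------------------------------------------------------------------

#' Add a balanced two-batch effect to simulated counts
#'
#' Splits each group's samples evenly over 2 batches (so batch is orthogonal
#' to the group factor) and perturbs the second batch: a multiplicative shift
#' of the overall feature counts, and an additive logit shift of the
#' unspliced proportion for a random feature subset chosen independently of
#' the DR labels.  Zero magnitudes leave the counts untouched.
#'
#' @param sim a bulk `sim_counts` object.
#' @param batch_lfc log fold change of batch 2's overall counts (default
#'   `log(2)`).
#' @param batch_logit_shift logit shift of batch 2's unspliced proportion for
#'   affected features (default 1).
#' @param batch_fraction fraction of features with the proportion shift.
#' @return the `sim_counts` object with perturbed counts; `truth` gains
#'   `is_batch_affected` and the object a `batch_of` sample map.
#' @export
apply_batch_design <- function(sim, batch_lfc = log(2), batch_logit_shift = 1,
                               batch_fraction = 0.2) {
  stopifnot(inherits(sim, "sim_counts"), sim$mode == "bulk")
  groups <- split(sim$samples, sim$group_of[sim$samples])
  if (any(lengths(groups) < 2))
    stop("batch design needs >= 2 samples per group")
  batch_of <- setNames(rep(1L, length(sim$samples)), sim$samples)
  for (g in groups) {
    half <- seq_len(floor(length(g) / 2))
    batch_of[g[half]] <- 2L      # balanced: same split rule in both groups
  }
  T <- length(sim$feature_ids)
  affected <- rep(FALSE, T)
  affected[sample.int(T, round(batch_fraction * T))] <- TRUE
  if (batch_lfc != 0 || batch_logit_shift != 0) {
    for (s in sim$samples[batch_of == 2L]) {
      X <- sim$counts[[s]]
      if (batch_lfc != 0) X <- round(X * exp(batch_lfc))
      if (batch_logit_shift != 0) {
        y <- rowSums(X)
        idx <- which(affected & y > 0)
        pu <- (X[idx, "U"] + 0.5) / (y[idx] + 1)
        pu2 <- plogis(qlogis(pu) + batch_logit_shift)
        X[idx, "U"] <- rbinom(length(idx), y[idx], pu2)
        X[idx, "S"] <- y[idx] - X[idx, "U"]
      }
      sim$counts[[s]] <- X
    }
  }
  sim$truth$is_batch_affected <- affected
  sim$batch_of <- batch_of
  sim
}

## ---------------------------------------------------------------------------
## scoring
## ---------------------------------------------------------------------------

#' Score a ranking against simulation truth
#'
#' Computes the ROC curve and its area (rank-based, ties by midrank), the
#' number of false positives among the top-N detections for a grid of N, and
#' the corresponding false-discovery proportions.
#'
#' @param score per-feature ranking score, higher = more confidently
#'   differential (e.g. `max(p, 1 - p)`, or `1 - wald_pvalue`).
#' @param is_dr logical ground-truth labels.
#' @param top_n grid of top-N cutoffs.
#' @return list with `auroc`, `roc` (data frame `fpr`, `tpr`) and `top`
#'   (data frame `n`, `fp`, `fdp`).
#' @export
score_methods <- function(score, is_dr, top_n = c(10, 20, 50, 100, 200)) {
  stopifnot(length(score) == length(is_dr))
  is_dr <- as.logical(is_dr)
  nP <- sum(is_dr); nN <- sum(!is_dr)
  r <- rank(score)
  auroc <- if (nP == 0 || nN == 0) NA_real_
  else (sum(r[is_dr]) - nP * (nP + 1) / 2) / (nP * nN)
  o <- order(-score, seq_along(score))
  lab <- is_dr[o]
  tpr <- cumsum(lab) / max(nP, 1)
  fpr <- cumsum(!lab) / max(nN, 1)
  top_n <- top_n[top_n <= length(score)]
  fp <- vapply(top_n, function(n) sum(!lab[seq_len(n)]), numeric(1))
  list(auroc = auroc,
       roc = data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
       top = data.frame(n = top_n, fp = fp, fdp = fp / top_n))
}
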