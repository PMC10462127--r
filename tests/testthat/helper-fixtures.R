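# small in-code fixtures shared across test files

# single-member-EC dataset built from an explicit count array X (T x V x N);
# the conjugate limit of the model: no multi-mapping, allocation deterministic
make_single_ec_ds <- function(X, mode = c("bulk-transcript", "sc-gene"),
                              groups = NULL, eff_len_S = 1, eff_len_U = 1) {
  mode <- match.arg(mode)
  T <- dim(X)[1]; V <- dim(X)[2]; N <- dim(X)[3]
  cat0 <- feature_catalog(sprintf("t%02d", seq_len(T)), mode,
                          eff_len_S = eff_len_S, eff_len_U = eff_len_U)
  members <- list(); cnt <- NULL
  for (v in seq_len(V)) for (f in seq_len(T)) {
    members[[length(members) + 1]] <- cbind(f, v)
    cnt <- rbind(cnt, X[f, v, ])
  }
  samples <- paste0("s", seq_len(N))
  if (is.null(groups)) groups <- setNames(rep("A", N), samples)
  ec_dataset(cat0, samples, groups, members, matrix(cnt, ncol = N,
                                                    dimnames = list(NULL, samples)))
}

# draw a small two-version count array from the hierarchical model itself
draw_model_counts <- function(T, N, dplus, pibar_u, depth = 300) {
  X <- array(0, dim = c(T, 2, N))
  for (i in seq_len(N)) {
    y <- rpois(T, depth)
    p <- rbeta(T, dplus * pibar_u, dplus * (1 - pibar_u))
    xu <- rbinom(T, y, p)
    X[, 1, i] <- y - xu
    X[, 2, i] <- xu
  }
  X
}

# random EC dataset generator for round-trip / property tests
random_ec_dataset <- function(n_features = 20, n_samples = 3, n_ecs = 50,
                              mode = "bulk-transcript", max_members = 3) {
  V <- if (mode == "bulk-transcript") 2 else 3
  cat0 <- feature_catalog(sprintf("f%03d", seq_len(n_features)), mode,
                          eff_len_S = runif(n_features, 500, 3000),
                          eff_len_U = runif(n_features, 800, 6000))
  members <- lapply(seq_len(n_ecs), function(e) {
    k <- sample.int(max_members, 1)
    fv <- sample.int(n_features * V, k)
    cbind(((fv - 1L) %% n_features) + 1L, ((fv - 1L) %/% n_features) + 1L)
  })
  counts <- matrix(rpois(n_ecs * n_samples, 20), n_ecs, n_samples)
  m <- merge_duplicate_ecs_for_tests(members, counts)
  samples <- paste0("s", seq_len(n_samples))
  groups <- setNames(rep(c("A", "B"), length.out = n_samples), samples)
  ec_dataset(cat0, samples, groups, m$members, m$counts)
}

merge_duplicate_ecs_for_tests <- function(members, counts) {
  keys <- vapply(members, function(m) {
    o <- order(m[, 1], m[, 2])
    paste(m[o, 1], m[o, 2], sep = ".", collapse = ";")
  }, character(1))
  idx <- split(seq_along(keys), keys)
  list(members = unname(lapply(idx, function(i) members[[i[1]]])),
       counts = do.call(rbind, lapply(idx, function(i)
         colSums(counts[i, , drop = FALSE]))))
}
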