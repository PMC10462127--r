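test_that("salmon eq_classes parsing resolves versions and conserves reads", {
  cat0 <- feature_catalog(c("t1", "t2"), "bulk-transcript",
                          eff_len_S = c(100, 200), eff_len_U = c(150, 250))

  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "1", "t1-S", "1\t0\t7"), f)
  ds <- read_salmon_eq_classes(f, cat0, "s1")
  expect_equal(length(ds$members), 1)
  expect_equal(unname(total_reads(ds)), 7)
  expect_equal(ds$members[[1]], cbind(1L, 1L), ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3", "2", "t1-S", "t1-U", "t2",
               "1\t0\t5", "2\t0\t1\t3"), f2)
  ds2 <- read_salmon_eq_classes(f2, cat0, "s1")
  expect_equal(length(ds2$members), 2)
  expect_equal(unname(total_reads(ds2)), 8)
  two <- ds2$members[[which(vapply(ds2$members, nrow, 1L) == 2)]]
  expect_equal(sort(two[, 2]), c(1L, 2L))  # spliced + unspliced of t1

  # unknown names and malformed counts are hard errors naming the line
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "1", "t9-S", "1\t0\t7"), f3)
  expect_error(read_salmon_eq_classes(f3, cat0, "s1"), "line 3.*t9")
  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "1", "t1-S", "1\t0\tseven"), f4)
  expect_error(read_salmon_eq_classes(f4, cat0, "s1"), "malformed")
})

test_that("salmon dialect round-trips an EC dataset written by write_ec_json", {
  set.seed(42)
  ds <- random_ec_dataset(n_features = 15, n_samples = 1, n_ecs = 30)
  f <- withr::local_tempfile(fileext = ".txt")
  write_salmon_eq_classes(ds, f, "s1")
  back <- read_salmon_eq_classes(f, ds$catalog, "s1", zero_based = TRUE)
  key <- function(d) {
    k <- vapply(d$members, function(m) {
      o <- order(m[, 1], m[, 2]); paste(m[o, 1], m[o, 2], collapse = ";")
    }, character(1))
    setNames(d$counts[, 1], k)[order(k)]
  }
  expect_equal(key(back), key(ds))
})

test_that("internal JSON format is lossless, including on random datasets", {
  cat0 <- feature_catalog("t1", "bulk-transcript")
  empty <- ec_dataset(cat0, "s1", c(s1 = "A"), list(),
                      matrix(0, 0, 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_ec_json(empty, f)
  expect_equal(length(read_ec_json(f)$members), 0)

  set.seed(7)
  for (mode in c("bulk-transcript", "sc-gene")) {
    ds <- random_ec_dataset(25, 3, 60, mode = mode)
    write_ec_json(ds, f)
    back <- read_ec_json(f)
    expect_equal(back$catalog$feature_ids, ds$catalog$feature_ids)
    expect_equal(back$catalog$eff_len_S, ds$catalog$eff_len_S)
    expect_equal(back$group_of, ds$group_of)
    expect_equal(back$members, ds$members, ignore_attr = TRUE)
    expect_equal(unname(back$counts), unname(ds$counts))
  }
  # schema violations are hard errors
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else"), bad, auto_unbox = TRUE)
  expect_error(read_ec_json(bad), "schema violation")
})

test_that("larger random dataset survives the JSON round-trip", {
  set.seed(99)
  ds <- random_ec_dataset(n_features = 200, n_samples = 4, n_ecs = 2000,
                          max_members = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_ec_json(ds, f)
  back <- read_ec_json(f)
  expect_equal(back$members, ds$members, ignore_attr = TRUE)
  expect_equal(unname(back$counts), unname(ds$counts))
  expect_equal(total_reads(back), total_reads(ds))
})

test_that("pseudo-bulk aggregation sums cells per sample without mixing", {
  genes <- c("g1", "g2")
  cells <- c("c1", "c2", "c3")
  mk <- function(v) Matrix::Matrix(v, 2, 3, sparse = TRUE,
                                   dimnames = list(genes, cells))
  cc <- list(S = mk(c(3, 0, 4, 1, 0, 5)), U = mk(c(1, 1, 0, 0, 2, 0)),
             A = mk(c(0, 0, 0, 0, 0, 0)))
  # c1, c2 in sample sa; c3 in sample sb
  assign <- data.frame(cell_id = cells, sample_id = c("sa", "sa", "sb"),
                       cluster_id = "k1", stringsAsFactors = FALSE)
  ds <- aggregate_pseudobulk(cc, assign, "k1")
  tot <- matrix(0, 2, 2, dimnames = list(genes, c("sa", "sb")))
  for (e in seq_along(ds$members)) {
    m <- ds$members[[e]]
    if (m[1, 2] == 1) tot[m[1, 1], ] <- tot[m[1, 1], ] + ds$counts[e, ]
  }
  expect_equal(tot["g1", "sa"], 7)          # 3 + 4, same sample
  expect_equal(tot["g1", "sb"], 0)          # no cross-sample mixing
  expect_equal(tot["g2", "sb"], 5)
  expect_equal(sum(ds$counts), sum(cc$S) + sum(cc$U) + sum(cc$A))
  expect_error(aggregate_pseudobulk(cc, assign, "nope"), "zero cells")
})

test_that("pseudo-bulk aggregation equals a brute-force groupby sum", {
  set.seed(11)
  G <- 12; ncell <- 50
  genes <- sprintf("g%02d", 1:G)
  cells <- sprintf("c%02d", 1:ncell)
  mk <- function() Matrix::Matrix(rpois(G * ncell, 2), G, ncell, sparse = TRUE,
                                  dimnames = list(genes, cells))
  cc <- list(S = mk(), U = mk(), A = mk())
  assign <- data.frame(cell_id = cells,
                       sample_id = sample(c("s1", "s2"), ncell, TRUE),
                       cluster_id = sample(c("k1", "k2"), ncell, TRUE),
                       stringsAsFactors = FALSE)
  ds <- aggregate_pseudobulk(cc, assign, "k1")
  # brute force oracle
  for (v in c("S", "U", "A")) {
    vi <- match(v, c("S", "U", "A"))
    for (s in ds$samples) {
      sel <- assign$cell_id[assign$cluster_id == "k1" & assign$sample_id == s]
      oracle <- Matrix::rowSums(cc[[v]][, sel, drop = FALSE])
      got <- numeric(G)
      for (e in seq_along(ds$members)) {
        m <- ds$members[[e]]
        if (m[1, 2] == vi) got[m[1, 1]] <- got[m[1, 1]] + ds$counts[e, s]
      }
      expect_equal(got, unname(oracle))
    }
  }
})

test_that("minimum-count filter uses per-group totals and is idempotent", {
  # 5 features with hand-computed EC-compatible group totals
  cat0 <- feature_catalog(paste0("t", 1:5), "bulk-transcript")
  samples <- c("a1", "a2", "b1", "b2")
  groups <- setNames(c("A", "A", "B", "B"), samples)
  members <- list(cbind(1L, 1L), cbind(2L, 1L), cbind(3L, 1L),
                  cbind(c(4L, 5L), c(1L, 1L)), cbind(5L, 2L))
  counts <- rbind(c(6, 6, 6, 5),    # t1: A=12, B=11 -> kept
                  c(6, 6, 5, 4),    # t2: A=12, B=9  -> dropped
                  c(2, 2, 9, 9),    # t3: A=4        -> dropped
                  c(5, 6, 6, 6),    # t4&t5 via shared EC: A=11, B=12
                  c(0, 1, 0, 0))    # t5 extra: A=12
  ds <- ec_dataset(cat0, samples, groups, members, counts)
  out <- filter_min_counts(ds, 10)
  expect_setequal(out$catalog$feature_ids, c("t1", "t4", "t5"))
  # mixed EC keeps surviving members; counts unchanged
  expect_equal(sort(unname(total_reads(out))),
               sort(unname(colSums(counts[c(1, 4, 5), ]))))
  # idempotence
  out2 <- filter_min_counts(out, 10)
  expect_equal(out2$catalog$feature_ids, out$catalog$feature_ids)
  expect_equal(unname(out2$counts), unname(out$counts))
})

test_that("USA-mode matrix reading accepts split and suffixed layouts", {
  dir <- withr::local_tempdir()
  genes <- c("g1", "g2"); cells <- c("c1", "c2", "c3")
  S <- Matrix::Matrix(c(1, 0, 2, 3, 0, 1), 2, 3, sparse = TRUE)
  U <- Matrix::Matrix(c(0, 1, 0, 0, 2, 0), 2, 3, sparse = TRUE)
  Matrix::writeMM(S, file.path(dir, "s.mtx"))
  Matrix::writeMM(U, file.path(dir, "u.mtx"))
  writeLines(genes, file.path(dir, "genes.tsv"))
  writeLines(cells, file.path(dir, "cells.tsv"))
  out <- read_usa_counts(file.path(dir, "s.mtx"), file.path(dir, "u.mtx"),
                         features = file.path(dir, "genes.tsv"),
                         barcodes = file.path(dir, "cells.tsv"))
  expect_equal(unname(as.matrix(out$S)), unname(as.matrix(S)))
  expect_equal(sum(out$A), 0)

  # single matrix with suffixed rows
  M <- rbind(as.matrix(S), as.matrix(U))
  Matrix::writeMM(Matrix::Matrix(M, sparse = TRUE), file.path(dir, "usa.mtx"))
  writeLines(c("g1-S", "g2-S", "g1-U", "g2-U"), file.path(dir, "genes2.tsv"))
  out2 <- read_usa_counts(file.path(dir, "usa.mtx"),
                          features = file.path(dir, "genes2.tsv"),
                          barcodes = file.path(dir, "cells.tsv"))
  expect_equal(unname(as.matrix(out2$U)), unname(as.matrix(U)))
})
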