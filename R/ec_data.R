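## ---------------------------------------------------------------------------
## Equivalence-class data model: feature catalog, EC dataset, readers/writers,
## pseudo-bulk aggregation and abundance filtering.
## ---------------------------------------------------------------------------

#' Feature catalog
#'
#' Describes the features (transcripts for bulk data, genes for single-cell
#' data) an analysis runs over, the splice versions present, and — for bulk
#' transcripts — the effective length of each splice version.  Effective
#' lengths enter the allocation of multi-mapping reads: the probability of
#' assigning a read to a transcript version is normalized by that version's
#' effective length so that longer transcripts are not favoured.
#'
#' @param feature_ids character vector of unique transcript/gene identifiers.
#' @param mode `"bulk-transcript"` (versions S, U) or `"sc-gene"`
#'   (versions S, U, A — spliced, unspliced, ambiguous).
#' @param eff_len_S,eff_len_U positive effective lengths per feature
#'   (bulk mode only; recycled if scalar).
#' @return an object of class `feature_catalog`.
#' @export
feature_catalog <- function(feature_ids,
                            mode = c("bulk-transcript", "sc-gene"),
                            eff_len_S = NULL, eff_len_U = NULL) {
  mode <- match.arg(mode)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  versions <- if (mode == "bulk-transcript") c("S", "U") else c("S", "U", "A")
  T <- length(feature_ids)
  if (mode == "bulk-transcript") {
    if (is.null(eff_len_S)) eff_len_S <- 1
    if (is.null(eff_len_U)) eff_len_U <- 1
    eff_len_S <- rep_len(as.numeric(eff_len_S), T)
    eff_len_U <- rep_len(as.numeric(eff_len_U), T)
    if (any(eff_len_S <= 0) || any(eff_len_U <= 0))
      stop("effective lengths must be > 0")
  } else {
    eff_len_S <- eff_len_U <- NULL
  }
  structure(list(feature_ids = feature_ids, mode = mode, versions = versions,
                 eff_len_S = eff_len_S, eff_len_U = eff_len_U),
            class = "feature_catalog")
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("<feature_catalog> ", length(x$feature_ids), " features, mode ",
      x$mode, " [", paste(x$versions, collapse = "/"), "]\n", sep = "")
  invisible(x)
}

## internal: effective-length matrix T x V (bulk) or NULL
catalog_len <- function(catalog) {
  if (catalog$mode != "bulk-transcript") return(NULL)
  cbind(S = catalog$eff_len_S, U = catalog$eff_len_U)
}

#' Equivalence-class dataset
#'
#' Container for observed equivalence-class (EC) counts.  An EC is the set of
#' (feature, splice-version) pairs a read is compatible with; reads sharing an
#' EC are interchangeable for inference.  `members` holds, per EC, a 2-column
#' integer matrix of (feature index, version index) pairs; `counts` is an
#' `n_ecs x n_samples` integer matrix.
#'
#' @param catalog a [feature_catalog()].
#' @param samples character vector of sample identifiers.
#' @param group_of named character vector mapping each sample to its group
#'   label (may contain `NA` when groups are not yet assigned).
#' @param members list of 2-column integer matrices (feature index,
#'   version index), one per EC, without duplicated pairs.
#' @param counts integer matrix of EC counts, ECs in rows, samples in columns.
#' @return an object of class `ec_dataset`.
#' @export
ec_dataset <- function(catalog, samples, group_of, members, counts) {
  stopifnot(inherits(catalog, "feature_catalog"))
  samples <- as.character(samples)
  counts <- as.matrix(counts)
  if (length(members) != nrow(counts))
    stop("members and counts disagree on the number of ECs")
  if (ncol(counts) != length(samples))
    stop("counts and samples disagree on the number of samples")
  colnames(counts) <- samples
  if (any(counts < 0)) stop("EC counts must be non-negative")
  T <- length(catalog$feature_ids); V <- length(catalog$versions)
  for (e in seq_along(members)) {
    m <- members[[e]]
    if (!is.matrix(m) || ncol(m) != 2 || nrow(m) < 1)
      stop("EC ", e, ": members must be a non-empty 2-column matrix")
    if (any(m[, 1] < 1 | m[, 1] > T)) stop("EC ", e, ": unknown feature index")
    if (any(m[, 2] < 1 | m[, 2] > V)) stop("EC ", e, ": unknown version index")
    if (anyDuplicated(m[, 1] + T * (m[, 2] - 1L)))
      stop("EC ", e, ": duplicated (feature, version) member")
  }
  group_of <- group_of[samples]
  names(group_of) <- samples
  structure(list(catalog = catalog, samples = samples,
                 group_of = group_of, members = members,
                 counts = counts),
            class = "ec_dataset")
}

#' @export
print.ec_dataset <- function(x, ...) {
  gr <- unique(stats::na.omit(x$group_of))
  cat("<ec_dataset> ", length(x$members), " ECs, ",
      length(x$catalog$feature_ids), " features, ",
      length(x$samples), " samples",
      if (length(gr)) paste0(" (groups: ", paste(gr, collapse = ", "), ")"),
      "; total reads ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

## canonical string key of an EC member set (sorted), used to merge duplicates
ec_key <- function(m) {
  o <- order(m[, 1], m[, 2])
  paste(m[o, 1], m[o, 2], sep = ".", collapse = ";")
}

## merge ECs with identical member sets by summing counts
merge_duplicate_ecs <- function(members, counts) {
  keys <- vapply(members, ec_key, character(1))
  if (!anyDuplicated(keys)) return(list(members = members, counts = counts))
  idx <- split(seq_along(keys), keys)
  members2 <- lapply(idx, function(i) members[[i[1]]])
  counts2 <- t(vapply(idx, function(i)
    colSums(counts[i, , drop = FALSE]), numeric(ncol(counts))))
  if (ncol(counts) == 1) counts2 <- matrix(counts2, ncol = 1)
  list(members = unname(members2), counts = unname(counts2))
}

#' Total EC-compatible reads per sample
#'
#' @param ds an [ec_dataset()].
#' @return named numeric vector of per-sample totals.
#' @export
total_reads <- function(ds) colSums(ds$counts)

## per-feature, per-group total count of all ECs that include any version of
## the feature (the abundance measure used by the minimum-count filter)
feature_group_totals <- function(ds) {
  groups <- sort(unique(stats::na.omit(ds$group_of)))
  T <- length(ds$catalog$feature_ids)
  out <- matrix(0, T, length(groups), dimnames = list(ds$catalog$feature_ids, groups))
  for (g in groups) {
    sg <- ds$samples[!is.na(ds$group_of) & ds$group_of == g]
    ce <- rowSums(ds$counts[, sg, drop = FALSE])
    for (e in seq_along(ds$members)) {
      f <- unique(ds$members[[e]][, 1])
      out[f, g] <- out[f, g] + ce[e]
    }
  }
  out
}

#' Filter features on a minimum per-group count
#'
#' Keeps a feature only if the total count of all equivalence classes that
#' contain any version of it reaches `min_count` in *each* group.  ECs whose
#' members are all dropped are removed; mixed ECs keep their surviving members
#' (counts unchanged).  The operation is idempotent.
#'
#' @param ds an [ec_dataset()] with two groups assigned.
#' @param min_count minimum per-group EC-compatible count (default 10).
#' @return the filtered [ec_dataset()].
#' @export
filter_min_counts <- function(ds, min_count = 10) {
  tot <- feature_group_totals(ds)
  if (ncol(tot) < 2) stop("filter_min_counts needs two groups assigned")
  keep <- rowSums(tot >= min_count) == ncol(tot)
  subset_features(ds, which(keep))
}

#' Subset an EC dataset to a set of features
#'
#' Drops all other features from the catalog, prunes them from EC member
#' lists, and removes ECs left without members.
#'
#' @param ds an [ec_dataset()].
#' @param idx integer indices (into the catalog) of features to keep.
#' @return an [ec_dataset()] over the reduced catalog.
#' @export
subset_features <- function(ds, idx) {
  idx <- sort(unique(as.integer(idx)))
  cat0 <- ds$catalog
  new_of_old <- integer(length(cat0$feature_ids))
  new_of_old[idx] <- seq_along(idx)
  catalog <- feature_catalog(cat0$feature_ids[idx], mode = cat0$mode,
                             eff_len_S = cat0$eff_len_S[idx],
                             eff_len_U = cat0$eff_len_U[idx])
  members <- vector("list", length(ds$members))
  keep_ec <- logical(length(ds$members))
  for (e in seq_along(ds$members)) {
    m <- ds$members[[e]]
    ok <- new_of_old[m[, 1]] > 0
    if (any(ok)) {
      keep_ec[e] <- TRUE
      members[[e]] <- cbind(new_of_old[m[ok, 1]], m[ok, 2, drop = TRUE])
    }
  }
  ec_dataset(catalog, ds$samples, ds$group_of,
             members[keep_ec], ds$counts[keep_ec, , drop = FALSE])
}

#' Subset an EC dataset to a set of samples
#'
#' @param ds an [ec_dataset()].
#' @param samples sample identifiers to keep.
#' @return an [ec_dataset()] restricted to those samples.
#' @export
subset_samples <- function(ds, samples) {
  stopifnot(all(samples %in% ds$samples))
  ec_dataset(ds$catalog, samples, ds$group_of[samples], ds$members,
             ds$counts[, samples, drop = FALSE])
}

#' Split a two-group dataset into its per-group datasets
#'
#' @param ds an [ec_dataset()] with exactly two group labels.
#' @return a named list of two [ec_dataset()]s (group labels sorted).
#' @export
split_groups <- function(ds) {
  groups <- sort(unique(stats::na.omit(ds$group_of)))
  if (length(groups) != 2) stop("expected exactly two groups, found ",
                                length(groups))
  out <- lapply(groups, function(g)
    subset_samples(ds, ds$samples[!is.na(ds$group_of) & ds$group_of == g]))
  names(out) <- groups
  out
}

#' Combine per-sample EC datasets over a common catalog
#'
#' Merges datasets sample-wise; ECs with identical member sets are unified
#' (a sample absent from a dataset contributes zero counts to its ECs).
#'
#' @param ds_list list of [ec_dataset()]s sharing the same catalog.
#' @return one [ec_dataset()] with the union of samples.
#' @export
combine_ec_datasets <- function(ds_list) {
  stopifnot(length(ds_list) >= 1)
  catalog <- ds_list[[1]]$catalog
  for (d in ds_list)
    if (!identical(d$catalog$feature_ids, catalog$feature_ids))
      stop("all datasets must share the same catalog")
  samples <- unlist(lapply(ds_list, function(d) d$samples))
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  group_of <- unlist(lapply(ds_list, function(d) d$group_of))
  keys <- character(0); members <- list()
  counts <- NULL
  for (d in ds_list) {
    k <- vapply(d$members, ec_key, character(1))
    new <- !(k %in% keys)
    if (any(new)) {
      members <- c(members, d$members[new])
      keys <- c(keys, k[new])
      if (!is.null(counts))
        counts <- rbind(counts, matrix(0, sum(new), ncol(counts)))
    }
    block <- matrix(0, length(keys), length(d$samples))
    block[match(k, keys), ] <- d$counts
    counts <- if (is.null(counts)) block else cbind(counts, block)
  }
  colnames(counts) <- samples
  ec_dataset(catalog, samples, group_of[samples], members, counts)
}

## ---------------------------------------------------------------------------
## salmon eq_classes.txt dialect
## ---------------------------------------------------------------------------

## parse a transcript name into (feature, version) under the suffix convention
parse_versioned_id <- function(nm, unspliced_suffix = "-U",
                               ambiguous_suffix = "-A",
                               spliced_suffix = "-S") {
  v <- rep("S", length(nm))
  f <- nm
  is_u <- endsWith(nm, unspliced_suffix)
  f[is_u] <- substr(nm[is_u], 1, nchar(nm[is_u]) - nchar(unspliced_suffix))
  v[is_u] <- "U"
  is_a <- !is_u & endsWith(nm, ambiguous_suffix)
  f[is_a] <- substr(nm[is_a], 1, nchar(nm[is_a]) - nchar(ambiguous_suffix))
  v[is_a] <- "A"
  is_s <- !is_u & !is_a & endsWith(nm, spliced_suffix)
  f[is_s] <- substr(nm[is_s], 1, nchar(nm[is_s]) - nchar(spliced_suffix))
  data.frame(feature = f, version = v, stringsAsFactors = FALSE)
}

#' Read one sample's equivalence classes in the salmon `eq_classes.txt` dialect
#'
#' Layout: number of transcripts, number of ECs, the transcript names (one per
#' line), then one line per EC: `k  idx_1 ... idx_k  count` with 0-based
#' transcript indices.  Unspliced/ambiguous versions are encoded by an
#' identifier suffix (default `-U` / `-A`; a `-S` suffix or no suffix marks
#' spliced).  Gzip-compressed files are accepted.
#'
#' @param path path to the file (plain or `.gz`).
#' @param catalog the [feature_catalog()] the names must resolve against.
#' @param sample_id identifier for this sample.
#' @param unspliced_suffix,ambiguous_suffix,spliced_suffix suffix convention.
#' @param zero_based are transcript indices 0-based (salmon's convention)?
#' @return a one-sample [ec_dataset()] (group label `NA`).
#' @export
read_salmon_eq_classes <- function(path, catalog, sample_id,
                                   unspliced_suffix = "-U",
                                   ambiguous_suffix = "-A",
                                   spliced_suffix = "-S",
                                   zero_based = TRUE) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  n_tr <- suppressWarnings(as.integer(lines[1]))
  n_ec <- suppressWarnings(as.integer(lines[2]))
  if (is.na(n_tr) || is.na(n_ec))
    stop("malformed header in ", path)
  if (length(lines) < 2 + n_tr + n_ec)
    stop("truncated file: expected ", 2 + n_tr + n_ec, " lines, found ",
         length(lines))
  nm <- lines[3:(2 + n_tr)]
  pv <- parse_versioned_id(nm, unspliced_suffix, ambiguous_suffix, spliced_suffix)
  fidx <- match(pv$feature, catalog$feature_ids)
  if (anyNA(fidx)) {
    bad <- which(is.na(fidx))[1]
    stop("line ", 2 + bad, ": unknown transcript name '", nm[bad], "'")
  }
  vidx <- match(pv$version, catalog$versions)
  if (anyNA(vidx)) {
    bad <- which(is.na(vidx))[1]
    stop("line ", 2 + bad, ": version '", pv$version[bad],
         "' not present in catalog mode ", catalog$mode)
  }
  members <- vector("list", n_ec)
  counts <- integer(n_ec)
  off <- 2 + n_tr
  for (e in seq_len(n_ec)) {
    tok <- strsplit(trimws(lines[off + e]), "[ \t]+")[[1]]
    k <- suppressWarnings(as.integer(tok[1]))
    if (is.na(k) || length(tok) != k + 2)
      stop("line ", off + e, ": malformed EC line")
    tr <- suppressWarnings(as.integer(tok[2:(k + 1)]))
    cnt <- suppressWarnings(as.numeric(tok[k + 2]))
    if (anyNA(tr) || is.na(cnt) || cnt < 0 || cnt != round(cnt))
      stop("line ", off + e, ": malformed count or index")
    if (zero_based) tr <- tr + 1L
    if (any(tr < 1 | tr > n_tr))
      stop("line ", off + e, ": transcript index out of range")
    members[[e]] <- cbind(fidx[tr], vidx[tr])
    counts[e] <- as.integer(cnt)
  }
  m <- merge_duplicate_ecs(members, matrix(counts, ncol = 1))
  ec_dataset(catalog, sample_id, setNames(NA_character_, sample_id),
             m$members, m$counts)
}

#' Write one sample of an EC dataset in the salmon `eq_classes.txt` dialect
#'
#' Inverse of [read_salmon_eq_classes()] for a single sample; spliced/unspliced
#' (/ambiguous) versions are written with `-S`/`-U`(/`-A`) suffixes.
#'
#' @param ds an [ec_dataset()].
#' @param path output file path.
#' @param sample_id which sample's counts to write (default: first).
#' @export
write_salmon_eq_classes <- function(ds, path, sample_id = ds$samples[1]) {
  catalog <- ds$catalog
  T <- length(catalog$feature_ids); V <- length(catalog$versions)
  nm <- as.vector(outer(catalog$feature_ids, catalog$versions, paste, sep = "-"))
  lines <- c(T * V, length(ds$members), nm)
  cnt <- ds$counts[, sample_id]
  for (e in seq_along(ds$members)) {
    m <- ds$members[[e]]
    idx0 <- (m[, 1] - 1L) + T * (m[, 2] - 1L)   # 0-based over the name grid
    lines <- c(lines, paste(c(nrow(m), idx0, cnt[e]), collapse = "\t"))
  }
  writeLines(as.character(lines), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## internal JSON format (lossless round-trip)
## ---------------------------------------------------------------------------

#' Write an EC dataset to the internal JSON format
#'
#' Versioned, lossless schema holding the catalog (ids, mode, effective
#' lengths), samples, group labels and all ECs with per-sample counts.
#'
#' @param ds an [ec_dataset()].
#' @param path output path.
#' @export
write_ec_json <- function(ds, path) {
  obj <- list(
    format = "diffreg-ec", schema_version = 1L,
    mode = ds$catalog$mode,
    feature_ids = ds$catalog$feature_ids,
    versions = ds$catalog$versions,
    eff_len_S = ds$catalog$eff_len_S,
    eff_len_U = ds$catalog$eff_len_U,
    samples = ds$samples,
    group_of = as.vector(ds$group_of),
    ec_members_feature = lapply(ds$members, function(m) as.integer(m[, 1])),
    ec_members_version = lapply(ds$members, function(m) as.integer(m[, 2])),
    ec_counts = lapply(seq_along(ds$members),
                       function(e) as.numeric(ds$counts[e, ]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read an EC dataset from the internal JSON format
#'
#' @param path path to a file written by [write_ec_json()].
#' @return an [ec_dataset()].
#' @export
read_ec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  for (field in c("format", "schema_version", "mode", "feature_ids",
                  "versions", "samples"))
    if (is.null(obj[[field]]))
      stop("schema violation at /", field, ": missing required field")
  if (!identical(obj$format, "diffreg-ec"))
    stop("schema violation at /format: not a diffreg EC file")
  catalog <- feature_catalog(obj$feature_ids,
                             mode = if (identical(obj$mode, "bulk-transcript"))
                               "bulk-transcript" else "sc-gene",
                             eff_len_S = obj$eff_len_S,
                             eff_len_U = obj$eff_len_U)
  nec <- length(obj$ec_members_feature)
  members <- vector("list", nec)
  for (e in seq_len(nec))
    members[[e]] <- cbind(as.integer(obj$ec_members_feature[[e]]),
                          as.integer(obj$ec_members_version[[e]]))
  counts <- if (nec == 0) {
    matrix(0, 0, length(obj$samples))
  } else {
    do.call(rbind, lapply(obj$ec_counts, as.numeric))
  }
  group_of <- obj$group_of
  if (is.null(group_of) || length(group_of) == 0)
    group_of <- rep(NA_character_, length(obj$samples))
  group_of <- as.character(group_of)
  names(group_of) <- obj$samples
  ec_dataset(catalog, obj$samples, group_of, members, counts)
}

#' Assign group labels to samples
#'
#' @param ds an [ec_dataset()].
#' @param group_of named character vector, `sample -> group label`.
#' @return the dataset with groups set.
#' @export
set_groups <- function(ds, group_of) {
  stopifnot(all(ds$samples %in% names(group_of)))
  ds$group_of <- setNames(as.character(group_of[ds$samples]), ds$samples)
  ds
}

## ---------------------------------------------------------------------------
## single-cell inputs: USA-mode matrices, cluster assignments, pseudo-bulk
## ---------------------------------------------------------------------------

#' Read spliced/unspliced/ambiguous single-cell count matrices
#'
#' Accepts either three MatrixMarket files (one per splice version, genes in
#' rows and cells in columns) or a single matrix whose row names carry
#' `-S`/`-U`/`-A` suffixes (USA convention).
#'
#' @param mtx_s,mtx_u,mtx_a paths to the three MTX files (`mtx_a` optional —
#'   a zero matrix is used when absent); or `mtx_s` alone with suffixed rows.
#' @param features,barcodes paths to TSV files with gene identifiers and cell
#'   barcodes (first column used).
#' @return list with sparse matrices `S`, `U`, `A` (genes x cells) and
#'   character vectors `genes`, `cells`.
#' @export
read_usa_counts <- function(mtx_s, mtx_u = NULL, mtx_a = NULL,
                            features, barcodes) {
  genes <- read.delim(features, header = FALSE)[[1]]
  cells <- read.delim(barcodes, header = FALSE)[[1]]
  if (is.null(mtx_u)) {
    m <- methods::as(Matrix::readMM(mtx_s), "CsparseMatrix")
    if (nrow(m) != length(genes))
      stop("feature file and matrix disagree on row count")
    pv <- parse_versioned_id(as.character(genes))
    base <- unique(pv$feature)
    pick <- function(v) {
      sel <- which(pv$version == v)
      out <- m[sel, , drop = FALSE]
      rownames(out) <- pv$feature[sel]
      out[match(base, rownames(out)), , drop = FALSE]
    }
    S <- pick("S"); U <- pick("U")
    A <- if (any(pv$version == "A")) pick("A") else
      Matrix::Matrix(0, length(base), ncol(m), sparse = TRUE)
    genes <- base
  } else {
    S <- methods::as(Matrix::readMM(mtx_s), "CsparseMatrix")
    U <- methods::as(Matrix::readMM(mtx_u), "CsparseMatrix")
    A <- if (is.null(mtx_a))
      Matrix::Matrix(0, nrow(S), ncol(S), sparse = TRUE)
    else methods::as(Matrix::readMM(mtx_a), "CsparseMatrix")
  }
  for (m in list(S, U, A))
    if (!all(dim(m) == c(length(genes), length(cells))))
      stop("matrix dimensions do not match features/barcodes")
  dimnames(S) <- dimnames(U) <- dimnames(A) <- list(genes, cells)
  list(S = S, U = U, A = A, genes = as.character(genes),
       cells = as.character(cells))
}

#' Read a cell-to-(sample, cluster) assignment table
#'
#' @param path TSV with columns `cell_id`, `sample_id`, `cluster_id`.
#' @return a data frame with those three character columns.
#' @export
read_cell_assignment <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character")
  need <- c("cell_id", "sample_id", "cluster_id")
  if (!all(need %in% names(df)))
    stop("assignment table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("cells must map to exactly one cluster")
  df[need]
}

#' Read an effective-lengths table
#'
#' @param path TSV with columns `feature_id`, `eff_len_S`, `eff_len_U`.
#' @return data frame of effective lengths per feature.
#' @export
read_eff_lengths <- function(path) {
  df <- read.delim(path, header = TRUE)
  need <- c("feature_id", "eff_len_S", "eff_len_U")
  if (!all(need %in% names(df)))
    stop("effective-length table must have columns ",
         paste(need, collapse = ", "))
  df[need]
}

#' Pseudo-bulk aggregation of single-cell counts for one cluster
#'
#' For each sample, sums the spliced/unspliced/ambiguous counts over all cells
#' assigned to `cluster`.  When per-cell equivalence classes are supplied
#' (an [ec_dataset()] whose "samples" are cell identifiers), their counts are
#' aggregated the same way and ECs with identical member sets are merged;
#' otherwise single-member ECs are constructed from the aggregated counts.
#'
#' @param cell_counts list with genes x cells matrices `S`, `U`, `A`
#'   (as returned by [read_usa_counts()] or the simulator).
#' @param assign data frame `cell_id`, `sample_id`, `cluster_id`.
#' @param cluster the cluster to aggregate.
#' @param ecs optional per-cell [ec_dataset()] over the gene catalog.
#' @param groups optional named vector `sample_id -> group label`.
#' @return an [ec_dataset()] in `sc-gene` mode, samples = sample ids.
#' @export
aggregate_pseudobulk <- function(cell_counts, assign, cluster, ecs = NULL,
                                 groups = NULL) {
  sel <- assign[assign$cluster_id == cluster, , drop = FALSE]
  if (nrow(sel) == 0) stop("cluster '", cluster, "' has zero cells")
  missing_cells <- setdiff(sel$cell_id, colnames(cell_counts$S))
  if (length(missing_cells))
    stop("cells missing from the count matrix: ",
         paste(head(missing_cells, 3), collapse = ", "))
  samples <- sort(unique(sel$sample_id))
  genes <- rownames(cell_counts$S)
  agg <- function(m) {
    out <- sapply(samples, function(s) {
      cs <- sel$cell_id[sel$sample_id == s]
      Matrix::rowSums(m[, cs, drop = FALSE])
    })
    matrix(out, nrow = length(genes), dimnames = list(genes, samples))
  }
  Xs <- agg(cell_counts$S); Xu <- agg(cell_counts$U); Xa <- agg(cell_counts$A)
  catalog <- feature_catalog(genes, mode = "sc-gene")
  group_of <- if (is.null(groups)) setNames(rep(NA_character_, length(samples)),
                                            samples)
  else setNames(as.character(groups[samples]), samples)

  if (!is.null(ecs)) {
    if (!identical(ecs$catalog$feature_ids, genes))
      stop("per-cell ECs must share the gene catalog")
    counts <- sapply(samples, function(s) {
      cs <- intersect(ecs$samples, sel$cell_id[sel$sample_id == s])
      rowSums(ecs$counts[, cs, drop = FALSE])
    })
    counts <- matrix(counts, nrow = length(ecs$members),
                     dimnames = list(NULL, samples))
    m <- merge_duplicate_ecs(ecs$members, counts)
    return(ec_dataset(catalog, samples, group_of, m$members, m$counts))
  }
  ## single-member ECs from the aggregated counts
  counts_to_single_ecs(list(S = Xs, U = Xu, A = Xa), catalog, samples, group_of)
}

## build an ec_dataset of single-member ECs from per-version count matrices
counts_to_single_ecs <- function(X, catalog, samples, group_of) {
  T <- length(catalog$feature_ids)
  members <- list(); counts <- NULL
  for (v in seq_along(catalog$versions)) {
    m <- X[[catalog$versions[v]]]
    nz <- which(rowSums(m) > 0)
    members <- c(members, lapply(nz, function(f) cbind(f, v)))
    counts <- rbind(counts, m[nz, , drop = FALSE])
  }
  if (is.null(counts)) counts <- matrix(0, 0, length(samples))
  dimnames(counts) <- list(NULL, samples)
  ec_dataset(catalog, samples, group_of, members, counts)
}
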