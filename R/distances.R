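#' Pairwise genetic distances with pairwise deletion
#'
#' `nei_li_dist()` computes the restriction-data distance of Nei & Li for
#' binary presence/absence markers: with `n_xy` loci where both samples carry
#' the band and `n_x`, `n_y` the per-sample band counts (over loci observed in
#' both samples), the similarity is the Dice coefficient
#' `S = 2 n_xy / (n_x + n_y)` and the distance `D = 1 - S` (or `-log(S)` with
#' `log_transform = TRUE`). Shared band absence carries no similarity. A pair
#' with `n_x + n_y = 0` (identical all-absent profiles) gets `D = 0`.
#'
#' `allele_sharing_dist()` computes the allele-sharing distance for diploid
#' genotypes: at each jointly observed locus the two unordered genotypes share
#' `s` alleles counted with multiplicity (`AA~AA -> 2`, `AA~AB -> 1`,
#' `AB~AB -> 2`, `AA~BB -> 0`, `AG~GT -> 1`), and
#' `D = 1 - sum(s) / (2 L_obs)`.
#'
#' Missing loci are deleted pairwise: each pair is scored over the loci where
#' both samples are observed. A pair with no jointly observed locus is an
#' error.
#'
#' @param x a `marker_tbl` (binary dialect for `nei_li_dist`, a genotype
#'   dialect for `allele_sharing_dist`).
#' @param log_transform use `-log(S)` instead of `1 - S` (Nei-Li only).
#' @return an object of class `pairwise_dist`: a list with the symmetric
#'   distance matrix `d`, the matrix `n_loci_used` of jointly observed locus
#'   counts, and `labels`.
#' @examples
#' m <- marker_table(data.frame(sample = c("a", "b", "c", "d"),
#'                              L1 = c(1, 1, 0, 1), L2 = c(1, 0, 1, 0),
#'                              L3 = c(0, 1, 1, 0), L4 = c(1, 1, 0, 0)),
#'                   dialect = "binary")
#' nei_li_dist(m)$d["a", "b"]   # 1 - 2*2/(3+3) = 1/3
#' @export
nei_li_dist <- function(x, log_transform = FALSE) {
  stopifnot(inherits(x, "marker_tbl"))
  if (marker_dialect(x) != "binary")
    stop("nei_li_dist requires the binary dialect, got ", marker_dialect(x))
  arr <- pair_arrays(x, log_transform = log_transform)
  dist_from_arrays(arr)
}

#' @rdname nei_li_dist
#' @export
allele_sharing_dist <- function(x) {
  stopifnot(inherits(x, "marker_tbl"))
  if (!marker_dialect(x) %in% c("snp_nucleotide", "genotype_code"))
    stop("allele_sharing_dist requires a genotype dialect, got ",
         marker_dialect(x))
  dist_from_arrays(pair_arrays(x))
}

# Distance appropriate for the dialect.
default_distance <- function(x) {
  if (marker_dialect(x) == "binary") "nei_li" else "allele_sharing"
}

# Precompute per-pair per-locus count matrices so that a bootstrap replicate
# reduces to matrix-vector products with the locus multiplicity vector.
# For binary data:   A[p, l]  = both samples carry the band (0/1)
#                    SXY[p, l] = band count of the pair (0, 1 or 2)
#                    O[p, l]  = both observed (0/1)
# For genotypes:     S[p, l]  = alleles shared with multiplicity (0, 1, 2)
#                    O[p, l]  = both observed (0/1)
# Pairs are ordered as combn(n, 2) columns: (1,2), (1,3), ..., (n-1,n).
pair_arrays <- function(x, log_transform = FALSE) {
  m <- marker_matrix(x)
  n <- nrow(m)
  labels <- rownames(m)
  pairs <- combn(n, 2L)
  P <- ncol(pairs)
  type <- if (marker_dialect(x) == "binary") "nei_li" else "allele_sharing"
  O <- matrix(0, P, ncol(m))
  if (type == "nei_li") {
    A <- matrix(0, P, ncol(m))
    SXY <- matrix(0, P, ncol(m))
    mm <- m
    obs <- !is.na(mm)
    mm[!obs] <- 0L
    for (p in seq_len(P)) {
      i <- pairs[1, p]; j <- pairs[2, p]
      o <- obs[i, ] & obs[j, ]
      O[p, ] <- o
      A[p, ] <- (mm[i, ] == 1L & mm[j, ] == 1L) & o
      SXY[p, ] <- (mm[i, ] + mm[j, ]) * o
    }
    arr <- list(type = type, A = A, SXY = SXY, O = O,
                log_transform = log_transform)
  } else {
    al <- genotype_alleles(m)
    a1 <- al$a1; a2 <- al$a2
    obs <- !is.na(a1)
    a1[!obs] <- -1L; a2[!obs] <- -2L
    S <- matrix(0, P, ncol(m))
    for (p in seq_len(P)) {
      i <- pairs[1, p]; j <- pairs[2, p]
      o <- obs[i, ] & obs[j, ]
      # max over the two perfect matchings of a 2x2 assignment equals the
      # multiset intersection size for allele pairs
      m1 <- (a1[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
      m2 <- (a1[i, ] == a2[j, ]) + (a2[i, ] == a1[j, ])
      O[p, ] <- o
      S[p, ] <- pmax(m1, m2) * o
    }
    arr <- list(type = type, S = S, O = O, log_transform = FALSE)
  }
  arr$pairs <- pairs
  arr$labels <- labels
  arr$L <- ncol(m)
  arr
}

# Split normalized genotype strings into two integer allele codes per cell.
genotype_alleles <- function(m) {
  if (is.numeric(m)) { # genotype_code dialect: 0 = AA, 1 = AB, 2 = BB
    a1 <- ifelse(m == 2L, 2L, 1L)
    a2 <- ifelse(m == 0L, 1L, 2L)
    a1[is.na(m)] <- NA_integer_; a2[is.na(m)] <- NA_integer_
    dim(a1) <- dim(m); dim(a2) <- dim(m)
  } else {
    code <- function(ch) match(ch, c("A", "C", "G", "T"))
    a1 <- matrix(code(substr(m, 1, 1)), nrow(m), ncol(m))
    a2 <- matrix(code(substr(m, 2, 2)), nrow(m), ncol(m))
  }
  list(a1 = a1, a2 = a2)
}

# Pair-vector distances given locus multiplicities w (default: original data).
# Returns NULL (instead of an error) for undefined pairs when `strict = FALSE`
# so the bootstrap can redraw.
pair_distances <- function(arr, w = NULL, strict = TRUE) {
  if (is.null(w)) w <- rep(1, arr$L)
  n_obs <- drop(arr$O %*% w)
  if (any(n_obs < 1)) {
    if (!strict) return(NULL)
    p <- which(n_obs < 1)[1]
    stop(sprintf("no jointly observed loci for pair (%s, %s)",
                 arr$labels[arr$pairs[1, p]], arr$labels[arr$pairs[2, p]]))
  }
  if (arr$type == "nei_li") {
    num <- 2 * drop(arr$A %*% w)
    den <- drop(arr$SXY %*% w)
    s <- ifelse(den == 0, 1, num / den)  # identical all-absent profiles: D = 0
    d <- if (arr$log_transform) -log(pmax(s, .Machine$double.eps)) else 1 - s
  } else {
    d <- 1 - drop(arr$S %*% w) / (2 * n_obs)
  }
  list(d = d, n_obs = n_obs)
}

# Assemble the symmetric matrices from the pair vectors.
dist_from_arrays <- function(arr, w = NULL) {
  pd <- pair_distances(arr, w, strict = TRUE)
  n <- length(arr$labels)
  d <- matrix(0, n, n, dimnames = list(arr$labels, arr$labels))
  nl <- matrix(arr$L, n, n, dimnames = list(arr$labels, arr$labels))
  idx <- cbind(arr$pairs[1, ], arr$pairs[2, ])
  d[idx] <- pd$d; d[idx[, 2:1]] <- pd$d
  nl[idx] <- pd$n_obs; nl[idx[, 2:1]] <- pd$n_obs
  structure(list(d = d, n_loci_used = nl, labels = arr$labels,
                 method = arr$type),
            class = "pairwise_dist")
}

# Restrict precomputed pair arrays to a subset of samples.
subset_arrays <- function(arr, keep_labels) {
  keep <- match(keep_labels, arr$labels)
  stopifnot(!anyNA(keep))
  sel <- arr$pairs[1, ] %in% keep & arr$pairs[2, ] %in% keep
  out <- arr
  for (f in intersect(c("A", "SXY", "O", "S"), names(arr)))
    out[[f]] <- arr[[f]][sel, , drop = FALSE]
  old <- arr$pairs[, sel, drop = FALSE]
  remap <- match(seq_along(arr$labels), keep)
  out$pairs <- matrix(remap[old], nrow = 2)
  out$labels <- arr$labels[keep]
  out
}

#' @export
print.pairwise_dist <- function(x, ...) {
  cat("Pairwise ", x$method, " distances, ", length(x$labels), " samples\n",
      sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' @export
as.matrix.pairwise_dist <- function(x, ...) x$d

#' @export
as.dist.pairwise_dist <- function(m, ...) stats::as.dist(m$d)

#' Tidy a pairwise distance object
#'
#' @param x a `pairwise_dist`.
#' @param ... unused.
#' @return a tibble with one row per unordered sample pair: `sample1`,
#'   `sample2`, `distance`, `n_loci_used`.
#' @method tidy pairwise_dist
#' @export
tidy.pairwise_dist <- function(x, ...) {
  n <- length(x$labels)
  pr <- combn(n, 2L)
  tibble::tibble(sample1 = x$labels[pr[1, ]], sample2 = x$labels[pr[2, ]],
                 distance = x$d[t(pr)], n_loci_used = x$n_loci_used[t(pr)])
}

#' Export a distance matrix as labelled TSV
#'
#' @param x a `pairwise_dist`.
#' @param file output path.
#' @export
write_dist_tsv <- function(x, file) {
  df <- data.frame(sample = x$labels, x$d, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
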