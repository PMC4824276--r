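#' Neighbour-joining tree
#'
#' Estimates an unrooted tree from a distance matrix with the Saitou-Nei
#' neighbour-joining algorithm (via [ape::nj()]). Negative branch lengths are
#' retained by default, as in common NJ implementations; `clamp = TRUE` sets
#' them to zero for display.
#'
#' @param d a `pairwise_dist`, `dist` or symmetric numeric matrix.
#' @param clamp clamp negative branch lengths to zero.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(d, clamp = FALSE) {
  m <- if (inherits(d, "pairwise_dist")) d$d else as.matrix(d)
  if (nrow(m) < 3L) stop("neighbour-joining needs at least 3 samples, got ",
                         nrow(m))
  tr <- ape::nj(m)
  if (clamp) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# All non-trivial bipartitions of a tree, canonicalized as the side not
# containing `ref` (default: lexicographically smallest leaf). Returns a
# character vector of keys (leaves sorted, ";"-joined); attribute "node" maps
# each key to the internal node number of the tree.
tree_biparts <- function(tree, ref = NULL) {
  labels <- tree$tip.label
  n <- length(labels)
  ref <- ref %||% min(labels)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  nodes <- integer(0)
  for (i in seq_along(pp)) {
    k <- bipart_key(labels[pp[[i]]], labels, ref)
    if (!is.na(k)) {
      keys <- c(keys, k)
      nodes <- c(nodes, n + i)
    }
  }
  dup <- duplicated(keys)  # zero-length root edges can duplicate a split
  structure(keys[!dup], node = nodes[!dup])
}

# Bootstrap a tree series from precomputed pair arrays.
#
# For each replicate, locus multiplicities are drawn with replacement under a
# seed derived from (series_seed, replicate); a replicate that leaves some
# pair without jointly observed loci is redrawn with the next derived seed
# (at most `max_redraw` times). Bipartition occurrences are tallied over the
# B bootstrap trees.
boot_series_from_arrays <- function(arr, B, series_seed, max_redraw = 100L,
                                    keep_trees = FALSE) {
  ref_pd <- dist_from_arrays(arr)
  ref_tree <- nj_tree(ref_pd)
  ref_leaf <- min(arr$labels)
  counts <- new.env(parent = emptyenv())
  trees <- if (keep_trees) vector("list", B) else NULL
  L <- arr$L
  for (r in seq_len(B)) {
    pd <- NULL
    tries <- 0L
    while (is.null(pd)) {
      if (tries > max_redraw)
        stop("bootstrap replicate ", r, ": no valid locus resample after ",
             max_redraw, " redraws (too much missing data)")
      tag <- if (tries == 0L) as.character(r) else paste0(r, ".retry", tries)
      idx <- with_seed(derive_seed(series_seed, tag),
                       sample.int(L, L, replace = TRUE))
      w <- tabulate(idx, nbins = L)
      pd <- pair_distances(arr, w, strict = FALSE)
      tries <- tries + 1L
    }
    n <- length(arr$labels)
    dm <- matrix(0, n, n, dimnames = list(arr$labels, arr$labels))
    ij <- cbind(arr$pairs[1, ], arr$pairs[2, ])
    dm[ij] <- pd$d; dm[ij[, 2:1]] <- pd$d
    tr <- nj_tree(dm)
    if (keep_trees) trees[[r]] <- tr
    for (k in tree_biparts(tr, ref_leaf))
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
  }
  cnt <- unlist(as.list(counts)) %||% integer(0)
  structure(list(ref_tree = ref_tree, ref_dist = ref_pd,
                 counts = cnt[order(names(cnt))],
                 B = B, labels = sort(arr$labels), ref_leaf = ref_leaf,
                 seed = series_seed, trees = trees),
            class = "boot_series")
}

#' Bootstrap tree series
#'
#' Builds the reference NJ tree from the full marker table and `B` bootstrap
#' NJ trees from locus resamples, and tallies how often each bipartition
#' occurs among the bootstrap trees.
#'
#' @param x a `marker_tbl`.
#' @param B number of bootstrap replicates.
#' @param seed integer seed; per-replicate seeds are derived from it.
#' @param distance `"nei_li"`, `"allele_sharing"`, or `NULL` to choose by
#'   dialect.
#' @param keep_trees retain the individual bootstrap trees.
#' @return an object of class `boot_series` with elements `ref_tree`,
#'   `counts` (named bipartition occurrence counts) and `B`.
#' @export
bootstrap_series <- function(x, B, seed, distance = NULL, keep_trees = FALSE) {
  stopifnot(inherits(x, "marker_tbl"), B >= 1)
  distance <- distance %||% default_distance(x)
  check_distance_dialect(x, distance)
  arr <- pair_arrays(x)
  boot_series_from_arrays(arr, B, seed, keep_trees = keep_trees)
}

check_distance_dialect <- function(x, distance) {
  ok <- switch(distance,
               nei_li = marker_dialect(x) == "binary",
               allele_sharing = marker_dialect(x) != "binary",
               stop("unknown distance: ", distance))
  if (!ok) stop("distance '", distance, "' does not apply to dialect '",
                marker_dialect(x), "'")
  invisible(TRUE)
}

#' Bootstrap support for the reference tree
#'
#' @param series a `boot_series`.
#' @return a tibble with one row per internal node of the reference tree:
#'   `node` (the [ape::phylo] node number), `clade` (";"-joined leaves of the
#'   canonical bipartition side) and `bs` (percent of bootstrap trees
#'   containing the bipartition, one decimal).
#' @export
support_on_reference <- function(series) {
  stopifnot(inherits(series, "boot_series"))
  keys <- tree_biparts(series$ref_tree, series$ref_leaf)
  cnt <- series$counts[keys]
  cnt[is.na(cnt)] <- 0L
  tibble::tibble(node = attr(keys, "node"), clade = as.character(keys),
                 bs = round(100 * as.numeric(cnt) / series$B, 1))
}

#' @export
print.boot_series <- function(x, ...) {
  cat("Bootstrap series: ", length(x$labels), " samples, B = ", x$B, ", ",
      length(x$counts), " distinct bipartitions\n", sep = "")
  invisible(x)
}

# Reference tree with bootstrap support as internal node labels.
support_labelled_tree <- function(series) {
  tr <- series$ref_tree
  keys <- tree_biparts(tr, series$ref_leaf)
  lab <- rep("", tr$Nnode)
  sup <- support_on_reference(series)
  lab[sup$node - length(tr$tip.label)] <- format(sup$bs, trim = TRUE)
  tr$node.label <- lab
  tr
}
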