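# Support accounting: mapping full-tree nodes into each taxon-jackknife
# analysis with support-carryover (SC) and NA semantics, assembling the
# nodes x exclusions support table, Tukey boxplot outlier detection, and
# custom / alternative node queries.

# Full-tree internal nodes. `key` is the canonical bipartition key used to
# look support up in the full series; `clade` is the node's leaf set oriented
# away from the outgroup (when one is given), which is what tables and signal
# classification report.
full_tree_nodes <- function(result, ref_root = NULL) {
  keys <- tree_biparts(result$full$ref_tree, result$full$ref_leaf)
  leaves <- result$full$ref_tree$tip.label
  sets <- lapply(keys, key_leaves)
  if (!is.null(ref_root))
    sets <- lapply(sets, function(s)
      if (ref_root %in% s) setdiff(leaves, s) else s)
  disp <- vapply(sets, function(s) paste(sort(s), collapse = ";"),
                 character(1))
  ord <- order(lengths(sets), disp)
  tibble::tibble(node_id = sprintf("N%02d", seq_along(keys)),
                 key = as.character(keys)[ord], clade = sets[ord],
                 clade_disp = disp[ord], clade_size = lengths(sets)[ord])
}

# Status of every full-tree node under one exclusion.
#
# Rooted at a reference leaf outside the excluded set, every internal node is
# a clade. If the excluded set E is itself a clade of the full tree, its
# sister clade S receives support carryover (SC) and is not scored. A node
# whose restriction C \ E has fewer than 2 leaves, is a trivial bipartition of
# the remaining leaf set, or duplicates the restriction of a smaller clade
# (the attachment node collapsing onto the sister) is marked NA. All other
# nodes are scored by the frequency of the restricted bipartition in the
# jackknife bootstrap series (0 if absent).
restrict_column <- function(nodes, excluded, leaves, series, ref_root = NULL) {
  leaves_left <- setdiff(leaves, excluded)
  # the clade lattice (and hence sisterhood) is oriented away from the
  # outgroup when one is given; otherwise away from a fixed remaining leaf
  ref_e <- ref_root %||% min(leaves_left)
  if (ref_e %in% excluded) ref_e <- min(leaves_left)
  # clades rooted away from the excluded set
  clades <- lapply(nodes$clade, function(cl)
    if (ref_e %in% cl) setdiff(leaves, cl) else cl)
  ckeys <- vapply(clades, function(cl) paste(sort(cl), collapse = ";"),
                  character(1))
  ekey <- paste(sort(excluded), collapse = ";")
  sister <- NULL
  if (length(excluded) == 1L || ekey %in% ckeys) {
    sup <- clades[vapply(clades, function(cl)
      all(excluded %in% cl) && length(cl) > length(excluded), logical(1))]
    if (length(sup)) {
      parent <- sup[[which.min(lengths(sup))]]
      sister <- setdiff(parent, excluded)
    }
  }
  ref_s <- min(series$labels)
  status <- character(nrow(nodes))
  skey <- rep(NA_character_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    cl <- clades[[i]]
    if (!is.null(sister) && setequal(cl, sister)) {
      status[i] <- "SC"
      next
    }
    r <- setdiff(cl, excluded)
    k <- if (length(r) >= 2L) bipart_key(r, leaves_left, ref_s) else NA_character_
    if (is.na(k)) {
      status[i] <- "NA"
    } else {
      status[i] <- "scored"
      skey[i] <- k
    }
  }
  # restriction of the SC node: scored nodes collapsing onto it are NA
  if (!is.null(sister) && length(sister) >= 2L) {
    sc_key <- bipart_key(sister, leaves_left, ref_s)
    if (!is.na(sc_key)) status[status == "scored" & skey == sc_key] <- "NA"
  }
  # among duplicated restrictions keep the smallest original clade
  sc_rows <- which(status == "scored")
  if (length(sc_rows) > 1L) {
    ord <- sc_rows[order(nodes$clade_size[sc_rows])]
    dup <- ord[duplicated(skey[ord])]
    status[dup] <- "NA"
  }
  bs <- rep(NA_real_, nrow(nodes))
  sel <- status == "scored"
  cnt <- series$counts[skey[sel]]
  cnt[is.na(cnt)] <- 0L
  bs[sel] <- round(100 * as.numeric(cnt) / series$B, 1)
  list(status = ifelse(sel, "bs", status), bs = bs)
}

#' Compile the support table of a homoplasy excess test
#'
#' Rows are the internal nodes of the full tree; columns are the full analysis
#' and every exclusion experiment. Each jackknife cell holds the bootstrap
#' support of the node's restricted bipartition in that series, or the marker
#' `SC` (support carryover: the node is sister to the excluded clade, so its
#' support increase is expected regardless of hybridization and is not
#' scored), or `NA` (the node collapses or becomes trivial once the excluded
#' samples are removed). A restricted bipartition absent from a series'
#' bootstrap trees scores 0, which is what makes lower outliers detectable.
#'
#' @param result a `het_result` from [run_het()].
#' @return a tibble of class `het_support` in long form with columns
#'   `node_id`, `clade` (";"-joined leaves), `clade_size`, `series` (`"full"`
#'   or an exclusion-set name), `marker` (`"bs"`, `"SC"`, `"NA"`) and `bs`
#'   (support percent, `NA` for marker cells). Attributes carry the grouping,
#'   exclusion sets and full tree.
#' @export
compile_support_table <- function(result) {
  stopifnot(inherits(result, "het_result"))
  og <- outgroup_label(result$grouping)
  ref_root <- if (!is.null(og))
    min(group_samples(result$grouping, og)) else NULL
  nodes <- full_tree_nodes(result, ref_root = ref_root)
  leaves <- result$labels
  full_sup <- support_on_reference(result$full)
  out <- list(tibble::tibble(
    node_id = nodes$node_id, clade = nodes$clade_disp,
    clade_size = nodes$clade_size, series = "full", marker = "bs",
    bs = full_sup$bs[match(nodes$key, full_sup$clade)]))
  for (i in seq_len(nrow(result$exclusions))) {
    nm <- result$exclusions$name[i]
    col <- restrict_column(nodes, result$exclusions$samples[[i]], leaves,
                           result$jackknife[[nm]], ref_root = ref_root)
    out[[i + 1L]] <- tibble::tibble(
      node_id = nodes$node_id, clade = nodes$clade_disp,
      clade_size = nodes$clade_size, series = nm,
      marker = col$status, bs = col$bs)
  }
  tbl <- dplyr::bind_rows(out)
  structure(tbl, class = c("het_support", class(tibble::tibble())),
            grouping = result$grouping, exclusions = result$exclusions,
            full_tree = result$full$ref_tree, B = result$B)
}

# Tukey hinges (fourths) and fences for one vector of support values.
tukey_fences <- function(v, k) {
  fn <- fivenum(v)
  q1 <- fn[2]; q3 <- fn[4]
  iqr <- q3 - q1
  c(q1 = q1, median = fn[3], q3 = q3, iqr = iqr,
    lower = q1 - k * iqr, upper = q3 + k * iqr)
}

#' Boxplot outlier detection on the support table
#'
#' For every node, the bootstrap support values observed across the
#' taxon-jackknife trees (`SC` and `NA` cells excluded, the full-tree column
#' not part of the sample) form a distribution summarised by Tukey hinges.
#' Values beyond `k` interquartile ranges from the hinges are outliers; upper
#' outliers are the homoplasy excess signal, annotated with the exclusion set
#' that produced them.
#'
#' @param table a `het_support` table from [compile_support_table()].
#' @param k the fence multiplier (`1.5` or `3` in published applications).
#' @param node_filter `"all"` or `"min_two_groups"` (report only nodes whose
#'   full-tree clade contains samples of at least two groups).
#' @param min_cells nodes with fewer numeric cells are skipped with a warning.
#' @return an object of class `het_outliers`: a list with `summary` (one row
#'   per node: hinges, IQR, fences, n) and `outliers` (one row per outlier:
#'   node, direction, value, causing exclusion set), plus the `k` used.
#' @export
boxplot_outliers <- function(table, k = 1.5, node_filter = c("all", "min_two_groups"),
                             min_cells = 5L) {
  stopifnot(inherits(table, "het_support"))
  node_filter <- match.arg(node_filter)
  if (k <= 0) stop("the IQR multiplier k must be positive, got ", k)
  grouping <- attr(table, "grouping")
  jack <- table[table$series != "full", ]
  full <- table[table$series == "full", ]
  nodes <- unique(table$node_id)
  if (node_filter == "min_two_groups") {
    keep <- vapply(nodes, function(nd) {
      cl <- key_leaves(full$clade[full$node_id == nd][1])
      length(unique(grouping$group[grouping$sample %in% cl])) >= 2L
    }, logical(1))
    nodes <- nodes[keep]
  }
  summaries <- list(); outs <- list()
  skipped <- character(0)
  for (nd in nodes) {
    rows <- jack[jack$node_id == nd & jack$marker == "bs", ]
    v <- rows$bs
    if (length(v) < min_cells) {
      skipped <- c(skipped, nd)
      next
    }
    f <- tukey_fences(v, k)
    summaries[[nd]] <- tibble::tibble(
      node_id = nd, clade = full$clade[full$node_id == nd][1],
      full_bs = full$bs[full$node_id == nd][1], n = length(v),
      q1 = unname(f["q1"]), median = unname(f["median"]),
      q3 = unname(f["q3"]), iqr = unname(f["iqr"]),
      lower_fence = unname(f["lower"]), upper_fence = unname(f["upper"]))
    hi <- v > f["upper"]; lo <- v < f["lower"]
    if (any(hi | lo)) {
      outs[[nd]] <- tibble::tibble(
        node_id = nd, clade = full$clade[full$node_id == nd][1],
        direction = ifelse(hi[hi | lo], "upper", "lower"),
        series = rows$series[hi | lo], bs = v[hi | lo],
        full_bs = full$bs[full$node_id == nd][1])
    }
  }
  if (length(skipped))
    warning("node(s) skipped with fewer than ", min_cells,
            " numeric cells: ", paste(skipped, collapse = ", "))
  summary_proto <- tibble::tibble(
    node_id = character(0), clade = character(0), full_bs = numeric(0),
    n = integer(0), q1 = numeric(0), median = numeric(0), q3 = numeric(0),
    iqr = numeric(0), lower_fence = numeric(0), upper_fence = numeric(0))
  outlier_proto <- tibble::tibble(
    node_id = character(0), clade = character(0), direction = character(0),
    series = character(0), bs = numeric(0), full_bs = numeric(0))
  structure(list(summary = dplyr::bind_rows(c(list(summary_proto), summaries)),
                 outliers = dplyr::bind_rows(c(list(outlier_proto), outs)),
                 k = k, node_filter = node_filter,
                 support = table),
            class = "het_outliers")
}

#' @export
print.het_outliers <- function(x, ...) {
  cat("Boxplot outlier report (k = ", x$k, ", ", nrow(x$summary),
      " nodes)\n", sep = "")
  if (nrow(x$outliers) == 0) cat("  no outliers\n")
  else print(x$outliers)
  invisible(x)
}

#' @rdname boxplot_outliers
#' @param x a `het_outliers` object.
#' @param ... unused.
#' @method tidy het_outliers
#' @export
tidy.het_outliers <- function(x, ...) x$outliers

#' @rdname boxplot_outliers
#' @method glance het_outliers
#' @export
glance.het_outliers <- function(x, ...) {
  tibble::tibble(k = x$k, n_nodes = nrow(x$summary),
                 n_upper = sum(x$outliers$direction == "upper"),
                 n_lower = sum(x$outliers$direction == "lower"))
}

#' Bootstrap support of a user-chosen node across all series
#'
#' Looks up the frequency of the bipartition defined by `leaves` in the
#' bootstrap trees of the full analysis and of every exclusion experiment,
#' whether or not the node occurs in any reference tree. Series whose excluded
#' samples intersect `leaves` are reported as `NA`.
#'
#' @param result a `het_result`.
#' @param leaves character vector (>= 2) of sample ids defining the node.
#' @return a tibble with columns `series`, `marker` and `bs`.
#' @export
query_custom_node <- function(result, leaves) {
  stopifnot(inherits(result, "het_result"))
  if (length(leaves) < 2L) stop("a node needs at least 2 leaves")
  unknown <- setdiff(leaves, result$labels)
  if (length(unknown)) stop("unknown sample(s): ",
                            paste(unknown, collapse = ", "))
  series_bs <- function(series, excluded) {
    if (length(intersect(leaves, excluded)))
      return(c(marker = "NA", bs = NA))
    key <- bipart_key(leaves, series$labels, min(series$labels))
    if (is.na(key)) return(c(marker = "NA", bs = NA))
    cnt <- series$counts[key] %||% NA
    if (is.na(cnt)) cnt <- 0L
    c(marker = "bs", bs = round(100 * as.numeric(cnt) / series$B, 1))
  }
  rows <- list(tibble::tibble(series = "full", marker = "bs",
                              bs = as.numeric(series_bs(result$full,
                                                        character(0))[["bs"]])))
  for (i in seq_len(nrow(result$exclusions))) {
    nm <- result$exclusions$name[i]
    r <- series_bs(result$jackknife[[nm]], result$exclusions$samples[[i]])
    rows[[i + 1L]] <- tibble::tibble(series = nm, marker = r[["marker"]],
                                     bs = as.numeric(r[["bs"]]))
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("het_node_query", class(out)),
            leaves = sort(leaves))
}

#' @rdname query_custom_node
#' @param object a `het_node_query` from [query_custom_node()].
#' @param k fence multiplier for the rendered boxplot.
#' @param ... unused.
#' @return `autoplot()`: a single-node boxplot of the jackknife support
#'   values with Tukey hinges and fences at `k` IQR; exclusion series beyond
#'   the fences are drawn and labelled as outliers.
#' @method autoplot het_node_query
#' @export
autoplot.het_node_query <- function(object, k = 1.5, ...) {
  v <- object[object$series != "full" & object$marker == "bs", ]
  if (nrow(v) < 2)
    return(ggplot2::ggplot() + ggplot2::labs(title = "Too few values"))
  f <- tukey_fences(v$bs, k)
  inside <- v$bs[v$bs >= f["lower"] & v$bs <= f["upper"]]
  node <- paste(attr(object, "leaves"), collapse = ";")
  box <- tibble::tibble(node = node, lo = min(inside), q1 = f[["q1"]],
                        med = f[["median"]], q3 = f[["q3"]],
                        hi = max(inside))
  outl <- v[v$bs < f["lower"] | v$bs > f["upper"], ]
  p <- ggplot2::ggplot(box, ggplot2::aes(y = .data$node)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(xmin = .data$lo, xlower = .data$q1, xmiddle = .data$med,
                   xupper = .data$q3, xmax = .data$hi),
      stat = "identity", orientation = "y", fill = "grey90") +
    ggplot2::geom_point(
      data = object[object$series == "full", ],
      ggplot2::aes(x = .data$bs, y = node), shape = 4) +
    ggplot2::labs(x = "bootstrap support (%)", y = NULL,
                  title = paste("Support for node", node)) +
    ggplot2::theme_minimal()
  if (nrow(outl))
    p <- p + ggplot2::geom_point(
      data = outl, ggplot2::aes(x = .data$bs, y = node,
                                colour = .data$series), size = 2) +
      ggplot2::labs(colour = "excluded set")
  p
}

#' Alternative-node registry
#'
#' Collects bipartitions that reach at least `min_support` percent in the
#' bootstrap trees of any series but are not restrictions of full-tree nodes
#' for that series. These are the nodes that appear only once a disruptive
#' taxon (e.g. a hybrid breaking the monophyly of its parent) is excluded.
#'
#' @param result a `het_result`.
#' @param min_support minimum support percent for inclusion.
#' @return a tibble with columns `series`, `clade` (";"-joined leaves) and
#'   `bs`.
#' @export
alt_nodes <- function(result, min_support = 50) {
  stopifnot(inherits(result, "het_result"))
  nodes <- full_tree_nodes(result)
  leaves <- result$labels
  rows <- list()
  known_full <- nodes$key
  cnt <- result$full$counts
  bs <- round(100 * as.numeric(cnt) / result$full$B, 1)
  sel <- bs >= min_support & !(names(cnt) %in% known_full)
  if (any(sel))
    rows[["full"]] <- tibble::tibble(series = "full",
                                     clade = names(cnt)[sel], bs = bs[sel])
  for (i in seq_len(nrow(result$exclusions))) {
    nm <- result$exclusions$name[i]
    series <- result$jackknife[[nm]]
    excl <- result$exclusions$samples[[i]]
    known <- character(0)
    left <- setdiff(leaves, excl)
    ref_s <- min(series$labels)
    for (j in seq_len(nrow(nodes))) {
      r <- setdiff(nodes$clade[[j]], excl)
      if (length(r) >= 2L) {
        k <- bipart_key(r, left, ref_s)
        if (!is.na(k)) known <- c(known, k)
      }
    }
    cnt <- series$counts
    bs <- round(100 * as.numeric(cnt) / series$B, 1)
    sel <- bs >= min_support & !(names(cnt) %in% known)
    if (any(sel))
      rows[[nm]] <- tibble::tibble(series = nm, clade = names(cnt)[sel],
                                   bs = bs[sel])
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- tibble::tibble(series = character(0),
                                        clade = character(0),
                                        bs = numeric(0))
  out
}
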