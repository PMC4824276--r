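#' Score outlier signals against simulated truth
#'
#' Classifies the upper boxplot outliers of a homoplasy excess test run on a
#' simulated data set with a known (planted) hybrid:
#'
#' * a *hybrid signal* is an upper outlier caused by excluding the hybrid
#'   group, at a node whose full-tree clade contains descendants of a parental
#'   lineage; a node containing descendants of both lineages counts once per
#'   indicated lineage;
#' * a *maximum-but-not-outlier signal* is a node containing parental
#'   descendants where the hybrid-exclusion cell is the unique row maximum
#'   across jackknife cells yet inside the fences;
#' * a *parent-exclusion signal* is an upper outlier caused by excluding a
#'   taxon of a parental lineage, at a node whose clade contained that taxon;
#' * every other upper outlier is a *false positive*, totalled at both fence
#'   multipliers and, separately, restricted to nodes joining at least two
#'   groups.
#'
#' The false-negative flag is set when no hybrid signal appears at the looser
#' fence. With `truth = NULL` (no hybrid simulated) all upper outliers are
#' false positives.
#'
#' @param outliers a `het_outliers` report from [boxplot_outliers()] at
#'   `k = 1.5` (the stricter `k = 3` report is recomputed internally from the
#'   same support table).
#' @param truth a truth record from [make_hybrid_dataset()], or `NULL`.
#' @return a one-row tibble of class `het_evaluation` with the signal and
#'   false-positive counts.
#' @export
classify_signals <- function(outliers, truth = NULL) {
  stopifnot(inherits(outliers, "het_outliers"))
  support <- outliers$support
  grouping <- attr(support, "grouping")
  exclusions <- attr(support, "exclusions")
  out15 <- outliers$outliers
  out3 <- suppressWarnings(
    boxplot_outliers(support, k = 3, node_filter = outliers$node_filter))$outliers
  up15 <- out15[out15$direction == "upper", , drop = FALSE]
  up3 <- out3[out3$direction == "upper", , drop = FALSE]

  two_group_nodes <- unique(vapply(unique(support$node_id), function(nd) {
    cl <- key_leaves(support$clade[support$node_id == nd][1])
    if (length(unique(grouping$group[grouping$sample %in% cl])) >= 2L) nd
    else NA_character_
  }, character(1)))
  two_group_nodes <- two_group_nodes[!is.na(two_group_nodes)]

  if (is.null(truth)) {
    res <- tibble::tibble(
      hybrid_outliers_k1.5 = NA_integer_, hybrid_outliers_k3 = NA_integer_,
      max_bs_not_outlier = NA_integer_, parent_exclusion_outliers = NA_integer_,
      fp_k1.5 = nrow(up15), fp_k3 = nrow(up3),
      fp_k1.5_min_two_groups = sum(up15$node_id %in% two_group_nodes),
      false_negative = NA)
    return(structure(res, class = c("het_evaluation", class(res))))
  }
  hyb <- truth$hybrid_group
  missing <- setdiff(c(hyb, unlist(truth$parents)), grouping$group)
  if (length(missing))
    stop("truth group(s) absent from run: ", paste(missing, collapse = ", "))
  lineage_samples <- lapply(truth$parents, function(tx)
    grouping$sample[grouping$group %in% tx])
  parent_groups <- unlist(truth$parents)

  node_lineages <- function(clade_key) {
    cl <- key_leaves(clade_key)
    names(lineage_samples)[vapply(lineage_samples, function(s)
      any(s %in% cl), logical(1))]
  }
  count_hybrid <- function(up) {
    sel <- up[up$series == hyb, , drop = FALSE]
    if (!nrow(sel)) return(list(n = 0L, rows = sel))
    lin <- lapply(sel$clade, node_lineages)
    keep <- lengths(lin) > 0L
    list(n = sum(lengths(lin)), rows = sel[keep, , drop = FALSE])
  }
  h15 <- count_hybrid(up15)
  h3 <- count_hybrid(up3)

  # parent-exclusion signals: outlier upon excluding a parental-lineage taxon
  # at a node that contained that taxon in the full tree
  parent_rows <- up15[up15$series %in% parent_groups, , drop = FALSE]
  parent_hit <- logical(nrow(parent_rows))
  for (i in seq_len(nrow(parent_rows))) {
    cl <- key_leaves(parent_rows$clade[i])
    parent_hit[i] <- any(group_samples(grouping, parent_rows$series[i]) %in% cl)
  }
  parent_sig <- parent_rows[parent_hit, , drop = FALSE]

  # unique row maximum for the hybrid-exclusion cell, inside the fences
  jack <- support[support$series != "full" & support$marker == "bs", ]
  max_bs <- 0L
  for (nd in unique(outliers$summary$node_id)) {
    rows <- jack[jack$node_id == nd, ]
    hrow <- rows[rows$series == hyb, ]
    if (nrow(hrow) != 1L) next
    others <- rows$bs[rows$series != hyb]
    if (!length(others) || hrow$bs <= max(others)) next
    lin <- node_lineages(rows$clade[1])
    if (!length(lin)) next
    fence <- outliers$summary$upper_fence[outliers$summary$node_id == nd]
    if (hrow$bs > fence) next  # already an outlier
    max_bs <- max_bs + length(lin)
  }

  is_signal <- function(up) {
    sig <- logical(nrow(up))
    for (i in seq_len(nrow(up))) {
      if (up$series[i] == hyb) {
        sig[i] <- length(node_lineages(up$clade[i])) > 0L
      } else if (up$series[i] %in% parent_groups) {
        cl <- key_leaves(up$clade[i])
        sig[i] <- any(group_samples(grouping, up$series[i]) %in% cl)
      }
    }
    sig
  }
  fp15 <- up15[!is_signal(up15), , drop = FALSE]
  fp3 <- up3[!is_signal(up3), , drop = FALSE]

  res <- tibble::tibble(
    hybrid_outliers_k1.5 = h15$n, hybrid_outliers_k3 = h3$n,
    max_bs_not_outlier = max_bs,
    parent_exclusion_outliers = nrow(parent_sig),
    fp_k1.5 = nrow(fp15), fp_k3 = nrow(fp3),
    fp_k1.5_min_two_groups = sum(fp15$node_id %in% two_group_nodes),
    false_negative = h15$n == 0L)
  structure(res, class = c("het_evaluation", class(res)))
}
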