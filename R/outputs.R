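# Tabular, tree and graphical output of a HET run.

support_wide <- function(table) {
  stopifnot(inherits(table, "het_support"))
  tbl <- tibble::as_tibble(table)
  tbl$cell <- ifelse(tbl$marker == "bs", format(tbl$bs, trim = TRUE),
                     tbl$marker)
  tidyr::pivot_wider(tbl[c("node_id", "clade", "series", "cell")],
                     names_from = "series", values_from = "cell")
}

#' Write all outputs of a homoplasy excess test
#'
#' Writes, into `outdir`: newick trees (`tree_full.nwk` plus one
#' `tree_excl_<set>.nwk` per exclusion, bootstrap support as internal node
#' labels), the wide support table (`support_table.tsv`, with literal `SC` and
#' `NA` markers), the outlier table (`outliers.tsv`), the alternative-node
#' registry (`alt_nodes.tsv`) and per-node boxplot graphics
#' (`boxplots.pdf`).
#'
#' @param result a `het_result`.
#' @param outdir output directory (created if needed).
#' @param k fence multiplier for the outlier table and plots.
#' @param node_filter passed to [boxplot_outliers()].
#' @param min_alt_support threshold for the alternative-node registry.
#' @param plots write the boxplot PDF.
#' @return (invisibly) the paths written.
#' @export
write_het_outputs <- function(result, outdir, k = 1.5,
                              node_filter = "all", min_alt_support = 50,
                              plots = TRUE) {
  stopifnot(inherits(result, "het_result"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  paths <- character(0)
  wr_tree <- function(series, file) {
    ape::write.tree(support_labelled_tree(series), file.path(outdir, file))
    file.path(outdir, file)
  }
  paths <- c(paths, wr_tree(result$full, "tree_full.nwk"))
  for (nm in names(result$jackknife))
    paths <- c(paths, wr_tree(result$jackknife[[nm]],
                              paste0("tree_excl_", nm, ".nwk")))
  table <- compile_support_table(result)
  f <- file.path(outdir, "support_table.tsv")
  write.table(support_wide(table), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, f)
  outl <- suppressWarnings(boxplot_outliers(table, k = k,
                                            node_filter = node_filter))
  f <- file.path(outdir, "outliers.tsv")
  ot <- outl$outliers
  if (nrow(ot)) {
    sm <- outl$summary[match(ot$node_id, outl$summary$node_id), ]
    ot <- dplyr::bind_cols(ot, sm[c("q1", "q3", "iqr")], k = k)
  }
  write.table(ot, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(outdir, "alt_nodes.tsv")
  write.table(alt_nodes(result, min_support = min_alt_support), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)
  if (plots && nrow(outl$summary)) {
    f <- file.path(outdir, "boxplots.pdf")
    p <- autoplot(outl)
    ggplot2::ggsave(f, p, width = 7,
                    height = max(2, 0.25 * nrow(outl$summary) + 1))
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Boxplot panel of node support across taxon-jackknife trees
#'
#' One horizontal box per full-tree node (Tukey hinges and fences as computed
#' by [boxplot_outliers()], so the boxes match the outlier calls exactly);
#' whiskers reach the most extreme values inside the fences, outliers are
#' drawn as labelled dots, and the full-tree support is marked with a cross.
#'
#' @param object a `het_outliers` report.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot het_outliers
#' @export
autoplot.het_outliers <- function(object, ...) {
  sm <- object$summary
  if (is.null(sm) || !nrow(sm))
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No nodes with enough support values"))
  support <- object$support
  jack <- support[support$series != "full" & support$marker == "bs", ]
  whisk <- do.call(rbind, lapply(seq_len(nrow(sm)), function(i) {
    v <- jack$bs[jack$node_id == sm$node_id[i]]
    inside <- v[v >= sm$lower_fence[i] & v <= sm$upper_fence[i]]
    data.frame(node_id = sm$node_id[i], lo = min(inside), hi = max(inside))
  }))
  sm <- dplyr::left_join(sm, whisk, by = "node_id")
  p <- ggplot2::ggplot(sm, ggplot2::aes(y = .data$node_id)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(xmin = .data$lo, xlower = .data$q1, xmiddle = .data$median,
                   xupper = .data$q3, xmax = .data$hi),
      stat = "identity", orientation = "y", fill = "grey90") +
    ggplot2::geom_point(ggplot2::aes(x = .data$full_bs), shape = 4) +
    ggplot2::labs(x = "bootstrap support (%)", y = "full-tree node",
                  title = paste0("Node support across taxon-jackknife trees",
                                 " (k = ", object$k, ")")) +
    ggplot2::theme_minimal()
  if (nrow(object$outliers)) {
    p <- p + ggplot2::geom_point(
      data = object$outliers,
      ggplot2::aes(x = .data$bs, y = .data$node_id, colour = .data$series),
      size = 2) +
      ggplot2::labs(colour = "excluded set")
  }
  p
}
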