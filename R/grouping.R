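#' Taxon grouping
#'
#' The taxon-jackknife removes one taxon (species, population, user-defined
#' group of samples) at a time, so every sample must belong to exactly one
#' group. Groups are either listed in a separate two-column file
#' (`sample<whitespace>group`) or encoded in the sample names themselves as a
#' final `"_"`-delimited suffix (`lib1_rupestris` belongs to group
#' `rupestris`). An optional outgroup (a group label) is used for display
#' rooting and is never excluded by the jackknife.
#'
#' @param samples character vector of sample ids the grouping must cover.
#' @param path optional path to a grouping file; when `NULL` the suffix
#'   convention is used.
#' @param outgroup optional group label.
#' @param suffix_sep separator for the suffix convention (default `"_"`).
#' @return a tibble of class `taxon_grouping` with columns `sample` and
#'   `group` and an `outgroup` attribute.
#' @examples
#' read_grouping(c("a_g1", "b_g1", "c_g2", "d_g2"))
#' @export
read_grouping <- function(samples, path = NULL, outgroup = NULL, suffix_sep = "_") {
  if (is.null(path)) {
    has_sep <- grepl(suffix_sep, samples, fixed = TRUE)
    if (!all(has_sep))
      stop("no group suffix in sample(s): ",
           paste(samples[!has_sep], collapse = ", "),
           " (and no grouping file given)")
    group <- vapply(strsplit(samples, suffix_sep, fixed = TRUE),
                    function(p) p[[length(p)]], character(1))
    tbl <- tibble::tibble(sample = samples, group = group)
  } else {
    df <- read.table(path, header = FALSE, col.names = c("sample", "group"),
                     colClasses = "character", comment.char = "#")
    missing <- setdiff(samples, df$sample)
    if (length(missing))
      stop("sample(s) missing from grouping file: ",
           paste(missing, collapse = ", "))
    tbl <- tibble::tibble(sample = samples,
                          group = df$group[match(samples, df$sample)])
  }
  taxon_grouping(tbl, outgroup = outgroup)
}

#' @rdname read_grouping
#' @param x a data frame with columns `sample` and `group`.
#' @export
taxon_grouping <- function(x, outgroup = NULL) {
  stopifnot(all(c("sample", "group") %in% names(x)))
  tbl <- tibble::as_tibble(x[c("sample", "group")])
  tbl$sample <- as.character(tbl$sample)
  tbl$group <- as.character(tbl$group)
  if (anyNA(tbl$group) || any(!nzchar(tbl$group))) {
    bad <- tbl$sample[is.na(tbl$group) | !nzchar(tbl$group)]
    stop("ungrouped sample(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(tbl$sample))
    stop("duplicated sample(s) in grouping: ",
         paste(unique(tbl$sample[duplicated(tbl$sample)]), collapse = ", "))
  if (!is.null(outgroup) && !outgroup %in% tbl$group)
    stop("outgroup '", outgroup, "' is not a group in the grouping")
  structure(tbl, class = c("taxon_grouping", class(tibble::tibble())),
            outgroup = outgroup)
}

#' @rdname read_grouping
#' @export
outgroup_label <- function(x) attr(x, "outgroup")

group_samples <- function(grouping, groups) {
  grouping$sample[grouping$group %in% groups]
}

ingroup_groups <- function(grouping) {
  setdiff(unique(grouping$group), outgroup_label(grouping))
}

#' Read explicit exclusion sets
#'
#' One set per line: `name<TAB>sample1,sample2,...`. Lines starting with `#`
#' are skipped.
#'
#' @param path path to the file.
#' @return a named list of character vectors of sample ids.
#' @export
read_exclusion_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed exclusion line: ", lines[which(bad)[1]])
  nm <- vapply(parts, `[[`, character(1), 1L)
  sets <- lapply(parts, function(p) strsplit(p[[2]], ",", fixed = TRUE)[[1]])
  if (any(lengths(sets) == 0L)) stop("empty exclusion set: ",
                                     nm[which(lengths(sets) == 0L)[1]])
  setNames(sets, nm)
}
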