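#' Marker tables
#'
#' A marker table holds samples-by-loci genetic marker data in one of three
#' dialects: `binary` presence/absence scores (0/1, e.g. AFLP or RFLP bands),
#' `snp_nucleotide` diploid SNP genotypes written as unordered nucleotide pairs
#' (`"AG"`, `"GG"`, ...; more than two alleles per locus are allowed), or
#' `genotype_code` bi-allelic genotypes coded 0 (AA), 1 (AB) and 2 (BB).
#' Missing entries are stored as `NA`; missingness applies to the whole
#' genotype of a sample at a locus.
#'
#' `marker_table()` builds a validated table from a data frame or matrix whose
#' first column (or rownames) identifies the samples; `read_marker_table()`
#' parses a whitespace/tab-separated text file with one sample per row, an
#' optional header row of locus names, and optional `#` comment lines.
#'
#' @param x a data frame or matrix of marker values; if a data frame, a
#'   `sample` column (or the first character column) gives sample ids.
#' @param dialect one of `"binary"`, `"snp_nucleotide"`, `"genotype_code"`.
#' @param missing_tokens character tokens mapped to `NA` when parsing.
#' @return a tibble of class `marker_tbl` with a `sample` column followed by
#'   one column per locus, and a `dialect` attribute.
#' @examples
#' m <- marker_table(
#'   data.frame(sample = c("a", "b", "c", "d"),
#'              L1 = c(1, 0, 1, 1), L2 = c(0, 0, 1, NA)),
#'   dialect = "binary")
#' n_loci(m)
#' @export
marker_table <- function(x, dialect = c("binary", "snp_nucleotide", "genotype_code"),
                         missing_tokens = c("?", "NA", "-", "??")) {
  dialect <- match.arg(dialect)
  if (is.matrix(x)) {
    samples <- rownames(x) %||% paste0("s", seq_len(nrow(x)))
    vals <- x
  } else {
    x <- as.data.frame(x)
    sc <- if ("sample" %in% names(x)) which(names(x) == "sample")[1] else 1L
    samples <- as.character(x[[sc]])
    vals <- as.matrix(x[-sc])
  }
  if (anyDuplicated(samples)) stop("duplicated sample ids: ",
                                   paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (length(samples) < 4L) stop("at least 4 samples are required, got ", length(samples))
  if (ncol(vals) < 1L) stop("no locus columns found")
  locus_names <- colnames(vals) %||% paste0("L", seq_len(ncol(vals)))
  tokens <- matrix(trimws(as.character(vals)), nrow = nrow(vals))
  tokens[tokens %in% missing_tokens | tokens == ""] <- NA_character_
  parsed <- parse_tokens(tokens, dialect, samples, locus_names)
  colnames(parsed) <- locus_names
  out <- dplyr::bind_cols(tibble::tibble(sample = samples),
                          tibble::as_tibble(parsed))
  new_marker_tbl(out, dialect)
}

new_marker_tbl <- function(tbl, dialect) {
  structure(tbl, class = c("marker_tbl", class(tibble::tibble())),
            dialect = dialect)
}

parse_tokens <- function(tokens, dialect, samples, locus_names) {
  if (dialect == "binary" || dialect == "genotype_code") {
    allowed <- if (dialect == "binary") c("0", "1") else c("0", "1", "2")
    bad <- which(!is.na(tokens) & !(tokens %in% allowed))
    if (length(bad)) {
      i <- ((bad[1] - 1L) %% nrow(tokens)) + 1L
      j <- ((bad[1] - 1L) %/% nrow(tokens)) + 1L
      stop(sprintf("illegal %s value '%s' at sample '%s', locus '%s'",
                   dialect, tokens[bad[1]], samples[i], locus_names[j]),
           call. = FALSE)
    }
    m <- matrix(as.integer(tokens), nrow = nrow(tokens))
    return(m)
  }
  up <- toupper(tokens)
  ok <- is.na(up) | grepl("^[ACGT]{2}$", up)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    i <- ((bad - 1L) %% nrow(tokens)) + 1L
    j <- ((bad - 1L) %/% nrow(tokens)) + 1L
    stop(sprintf("illegal genotype '%s' at sample '%s', locus '%s'",
                 tokens[bad], samples[i], locus_names[j]), call. = FALSE)
  }
  # normalize to unordered pairs: "GA" is stored as "AG"
  norm <- vapply(up, function(g) {
    if (is.na(g)) return(NA_character_)
    paste(sort(strsplit(g, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  matrix(norm, nrow = nrow(tokens))
}

#' @rdname marker_table
#' @param path path to a text file.
#' @param header `"auto"` (default) detects a header row of locus names by
#'   checking whether its tokens are valid marker values; `"present"` /
#'   `"none"` force the choice.
#' @export
read_marker_table <- function(path, dialect = c("binary", "snp_nucleotide", "genotype_code"),
                              missing_tokens = c("?", "NA", "-", "??"),
                              header = c("auto", "none", "present")) {
  dialect <- match.arg(dialect)
  header <- match.arg(header)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no data rows in ", path)
  rows <- strsplit(lines, "[ \t]+")
  valid_value <- function(tok) {
    tok %in% missing_tokens |
      switch(dialect,
             binary = tok %in% c("0", "1"),
             genotype_code = tok %in% c("0", "1", "2"),
             snp_nucleotide = grepl("^[ACGTacgt]{2}$", tok))
  }
  has_header <- switch(header,
    present = TRUE,
    none = FALSE,
    auto = length(rows) > 1L && !all(valid_value(rows[[1]][-1])))
  locus_names <- NULL
  if (has_header) {
    locus_names <- rows[[1]][-1]
    rows <- rows[-1]
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != stats::median(lens))[1]
    stop(sprintf("ragged row %d ('%s'): %d fields where %d expected",
                 bad, rows[[bad]][1], lens[bad], stats::median(lens)))
  }
  samples <- vapply(rows, `[[`, character(1), 1L)
  vals <- do.call(rbind, lapply(rows, `[`, -1L))
  if (is.null(locus_names)) locus_names <- paste0("L", seq_len(ncol(vals)))
  if (length(locus_names) != ncol(vals))
    stop("header has ", length(locus_names), " locus names but rows have ",
         ncol(vals), " values")
  colnames(vals) <- locus_names
  rownames(vals) <- samples
  marker_table(vals, dialect, missing_tokens)
}

#' @rdname marker_table
#' @param file output path; missing values are written as `"?"`.
#' @export
write_marker_table <- function(x, file) {
  stopifnot(inherits(x, "marker_tbl"))
  m <- marker_matrix(x)
  tok <- matrix(as.character(m), nrow = nrow(m), dimnames = dimnames(m))
  tok[is.na(tok)] <- "?"
  df <- data.frame(sample = rownames(m), tok, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname marker_table
#' @export
marker_dialect <- function(x) attr(x, "dialect")

#' @rdname marker_table
#' @export
n_loci <- function(x) ncol(x) - 1L

# samples x loci matrix with sample rownames
marker_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, -1, drop = FALSE])
  rownames(m) <- x$sample
  m
}

matrix_to_marker <- function(m, dialect) {
  marker_table(m, dialect)
}

#' Resample loci with replacement
#'
#' Draws `n_loci(x)` locus columns uniformly with replacement (the locus
#' bootstrap underlying node support), keeping all samples. Deterministic for a
#' fixed seed.
#'
#' @param x a `marker_tbl`.
#' @param seed integer seed.
#' @return a `marker_tbl` with the same dimensions.
#' @export
resample_loci <- function(x, seed) {
  stopifnot(inherits(x, "marker_tbl"))
  L <- n_loci(x)
  idx <- with_seed(seed, sample.int(L, L, replace = TRUE))
  m <- marker_matrix(x)[, idx, drop = FALSE]
  colnames(m) <- make.unique(colnames(m))
  marker_table(m, marker_dialect(x))
}
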