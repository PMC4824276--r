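#' Taxon-jackknife exclusion sets
#'
#' Builds the exclusion experiments of a homoplasy excess test: one set per
#' ingroup group (the outgroup is never excluded), plus optional user-defined
#' custom sets, plus `random_pairs` sets of two individuals drawn from two
#' different ingroup groups without repeating a previously emitted pair.
#'
#' @param grouping a `taxon_grouping`.
#' @param custom named list of character vectors of sample ids, e.g. from
#'   [read_exclusion_file()].
#' @param random_pairs number of random two-individual cross-group sets.
#' @param seed integer seed for the random pairs.
#' @return a tibble of class `exclusion_sets` with columns `name`, `kind`
#'   (`group`, `custom` or `random_pair`) and `samples` (list column).
#' @examples
#' g <- read_grouping(c("a1_t1", "a2_t1", "b1_t2", "b2_t2", "c1_t3", "c2_t3"))
#' make_exclusion_sets(g)
#' @export
make_exclusion_sets <- function(grouping, custom = NULL, random_pairs = 0L,
                                seed = 1L) {
  stopifnot(inherits(grouping, "taxon_grouping"))
  ing <- ingroup_groups(grouping)
  tbl <- tibble::tibble(
    name = ing, kind = "group",
    samples = lapply(ing, function(g) group_samples(grouping, g)))
  if (!is.null(custom)) {
    if (is.null(names(custom)) || any(!nzchar(names(custom))))
      stop("custom exclusion sets must be named")
    ok <- vapply(custom, function(s) all(s %in% grouping$sample), logical(1))
    if (!all(ok))
      stop("custom set(s) with unknown samples: ",
           paste(names(custom)[!ok], collapse = ", "))
    og <- group_samples(grouping, outgroup_label(grouping) %||% character(0))
    hit <- vapply(custom, function(s) any(s %in% og), logical(1))
    if (any(hit))
      stop("custom set(s) include outgroup samples: ",
           paste(names(custom)[hit], collapse = ", "))
    tbl <- dplyr::bind_rows(tbl, tibble::tibble(
      name = names(custom), kind = "custom", samples = unname(custom)))
  }
  if (random_pairs > 0L) {
    ing_samples <- grouping$sample[grouping$group %in% ing]
    grp <- grouping$group[match(ing_samples, grouping$sample)]
    all_pairs <- combn(seq_along(ing_samples), 2L)
    cross <- grp[all_pairs[1, ]] != grp[all_pairs[2, ]]
    all_pairs <- all_pairs[, cross, drop = FALSE]
    if (random_pairs > ncol(all_pairs))
      stop("requested ", random_pairs, " random pairs but only ",
           ncol(all_pairs), " distinct cross-group pairs exist")
    pick <- with_seed(derive_seed(seed, "random_pairs"),
                      sample.int(ncol(all_pairs), random_pairs))
    sets <- lapply(pick, function(p) ing_samples[all_pairs[, p]])
    tbl <- dplyr::bind_rows(tbl, tibble::tibble(
      name = paste0("pair", seq_len(random_pairs)), kind = "random_pair",
      samples = sets))
  }
  if (anyDuplicated(tbl$name))
    stop("duplicated exclusion set names: ",
         paste(unique(tbl$name[duplicated(tbl$name)]), collapse = ", "))
  structure(tbl, class = c("exclusion_sets", class(tibble::tibble())))
}

#' Run a homoplasy excess test
#'
#' Computes the full bootstrap tree series and one series per exclusion set:
#' the jackknife matrices are the full matrix restricted to the remaining
#' samples (loci are not re-filtered for polymorphism after exclusion, so all
#' series resample the same locus universe). Per-series seeds are derived from
#' the master seed and the set name, so results are identical regardless of
#' execution order or parallelism.
#'
#' @param x a `marker_tbl`.
#' @param grouping a `taxon_grouping` covering all samples of `x`.
#' @param B bootstrap replicates per series (>= 100 recommended).
#' @param seed master integer seed.
#' @param distance `"nei_li"`, `"allele_sharing"` or `NULL` (choose by
#'   dialect).
#' @param exclusions an `exclusion_sets` tibble; default: one set per ingroup
#'   group plus `random_pairs` random cross-group pairs.
#' @param custom named list of custom exclusion sets.
#' @param random_pairs number of random two-individual exclusion sets.
#' @param threads run exclusion series in parallel via forked processes
#'   (results are independent of `threads`).
#' @return an object of class `het_result` holding the full `boot_series`,
#'   one series per exclusion set, and run metadata.
#' @export
run_het <- function(x, grouping, B = 1000L, seed = 1L, distance = NULL,
                    exclusions = NULL, custom = NULL, random_pairs = 0L,
                    threads = 1L) {
  stopifnot(inherits(x, "marker_tbl"), inherits(grouping, "taxon_grouping"))
  missing <- setdiff(x$sample, grouping$sample)
  if (length(missing))
    stop("samples without group: ", paste(missing, collapse = ", "))
  grouping <- taxon_grouping(grouping[match(x$sample, grouping$sample), ],
                             outgroup = outgroup_label(grouping))
  if (B < 100L)
    warning("B = ", B, " bootstrap replicates; node support will be coarse")
  n_ing <- length(ingroup_groups(grouping))
  if (n_ing < 7L)
    warning(n_ing, " ingroup groups; boxplot outlier detection is ",
            "unreliable with fewer than 7 taxa")
  distance <- distance %||% default_distance(x)
  check_distance_dialect(x, distance)
  exclusions <- exclusions %||%
    make_exclusion_sets(grouping, custom = custom,
                        random_pairs = random_pairs, seed = seed)
  for (i in seq_len(nrow(exclusions))) {
    left <- setdiff(x$sample, exclusions$samples[[i]])
    if (length(left) < 3L)
      stop("exclusion set '", exclusions$name[i],
           "' leaves fewer than 3 samples")
  }
  arr <- pair_arrays(x)
  run_one <- function(i) {
    if (i == 0L)
      boot_series_from_arrays(arr, B, derive_seed(seed, "full"))
    else
      boot_series_from_arrays(
        subset_arrays(arr, setdiff(x$sample, exclusions$samples[[i]])),
        B, derive_seed(seed, "excl", exclusions$name[i]))
  }
  idx <- 0:nrow(exclusions)
  series <- if (threads > 1L)
    parallel::mclapply(idx, run_one, mc.cores = threads)
  else
    lapply(idx, run_one)
  err <- vapply(series, inherits, logical(1), "try-error")
  if (any(err)) stop(attr(series[[which(err)[1]]], "condition")$message)
  structure(list(full = series[[1]],
                 jackknife = setNames(series[-1], exclusions$name),
                 exclusions = exclusions, grouping = grouping,
                 B = B, seed = seed, distance = distance,
                 dialect = marker_dialect(x), labels = x$sample),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat("Homoplasy excess test result\n",
      "  samples: ", length(x$labels), " (", x$dialect, ", ",
      x$distance, " distance)\n",
      "  bootstrap replicates: ", x$B, " per series\n",
      "  series: full + ", nrow(x$exclusions), " exclusions\n", sep = "")
  invisible(x)
}

#' @rdname run_het
#' @param x a `het_result`.
#' @param ... unused.
#' @return `glance()`: a one-row tibble with run metadata and the mean
#'   bootstrap support over internal nodes of the full tree.
#' @method glance het_result
#' @export
glance.het_result <- function(x, ...) {
  sup <- support_on_reference(x$full)
  tibble::tibble(n_samples = length(x$labels),
                 n_groups = length(unique(x$grouping$group)),
                 dialect = x$dialect, distance = x$distance, B = x$B,
                 n_series = nrow(x$exclusions) + 1L,
                 mean_full_bs = mean(sup$bs), seed = x$seed)
}

#' @rdname run_het
#' @method tidy het_result
#' @export
tidy.het_result <- function(x, ...) {
  compile_support_table(x)
}
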