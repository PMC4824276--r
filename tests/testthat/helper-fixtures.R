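# Shared fixtures and independent oracles.

# small binary marker table; rows named a..d
toy_binary <- function() {
  marker_table(data.frame(sample = c("a", "b", "c", "d"),
                          L1 = c(1, 1, 0, 1), L2 = c(1, 0, 1, 1),
                          L3 = c(0, 1, 1, 1), L4 = c(1, 1, 0, 0)),
               dialect = "binary")
}

# brute-force Nei-Li on two 0/1 vectors with NA, pairwise deletion
oracle_nei_li <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  stopifnot(length(x) >= 1)
  nxy <- sum(x == 1 & y == 1)
  nx <- sum(x == 1); ny <- sum(y == 1)
  if (nx + ny == 0) return(0)
  1 - 2 * nxy / (nx + ny)
}

# brute-force allele sharing on two character genotype vectors ("AG", NA, ...)
oracle_allele_sharing <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  stopifnot(length(x) >= 1)
  shared <- mapply(function(g1, g2) {
    a <- strsplit(g1, "")[[1]]; b <- strsplit(g2, "")[[1]]
    s <- 0
    for (al in a) {
      hit <- match(al, b)
      if (!is.na(hit)) { s <- s + 1; b <- b[-hit] }
    }
    s
  }, x, y)
  1 - sum(shared) / (2 * length(x))
}

# brute-force Tukey hinge / fence / outlier scan
oracle_tukey_outliers <- function(v, k) {
  s <- sort(v)
  n <- length(s)
  half <- function(z) {
    m <- length(z)
    if (m %% 2 == 1) z[(m + 1) / 2] else mean(z[m / 2 + 0:1])
  }
  lowhalf <- s[1:ceiling(n / 2)]
  highhalf <- s[floor(n / 2 + 1):n]
  q1 <- half(lowhalf); q3 <- half(highhalf)
  iqr <- q3 - q1
  list(q1 = q1, q3 = q3,
       upper = v[v > q3 + k * iqr], lower = v[v < q1 - k * iqr])
}

# random unrooted tree with positive branch lengths and its additive distances
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# unrooted bipartition set of a phylo, as canonical keys
bipart_set <- function(tree) {
  sort(as.character(hetscreen:::tree_biparts(tree)))
}

# one-population model with n diploid individuals
one_pop_model <- function(theta, n_individuals = 1L) {
  species_tree_model(tibble::tibble(label = "pop", parent = 0L, time = 0,
                                    theta = theta),
                     theta = theta, n_individuals = n_individuals)
}

# two-taxon model with split time t
two_taxon_model <- function(theta, t, n_individuals = 1L) {
  species_tree_model(
    tibble::tibble(label = c("root", "p1", "p2"), parent = c(0L, 1L, 1L),
                   time = c(t, 0, 0), theta = theta),
    theta = theta, n_individuals = n_individuals)
}

# binary ladder data set with one sample per group (suffix grouping
# "s_<g>"): perfectly compatible characters supporting the nested splits
# {g1,g2}, {g1..g3}, ..., {g1..g(n-2)}, plus one private band per sample so
# no two rows are identical
caterpillar_binary <- function(n_groups = 6L, reps = 20L) {
  splits <- lapply(2:(n_groups - 2L), function(j)
    as.integer(seq_len(n_groups) <= j))
  chars <- do.call(cbind, splits)
  m <- cbind(chars[, rep(seq_len(ncol(chars)), reps)],
             diag(n_groups))
  rownames(m) <- paste0("s_g", seq_len(n_groups))
  colnames(m) <- paste0("L", seq_len(ncol(m)))
  marker_table(m, dialect = "binary")
}

suppress_small_run_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("bootstrap replicates|ingroup groups|numeric cells",
              conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
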