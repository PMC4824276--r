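# restrict_column is exercised directly on a hand-built tree so the SC/NA
# semantics are pinned down independently of any bootstrap run.

fake_series <- function(labels, counts = integer(0), B = 100) {
  structure(list(labels = sort(labels), counts = counts, B = B,
                 ref_leaf = min(labels)),
            class = "boot_series")
}

fig_nodes <- function() {
  tr <- ape::read.tree(text = "(((A,B),C),(D,E));")
  keys <- hetscreen:::tree_biparts(tr)
  sets <- lapply(as.character(keys), hetscreen:::key_leaves)
  tibble::tibble(node_id = c("N1", "N2"), key = as.character(keys),
                 clade = sets, clade_size = lengths(sets))
}

test_that("excluding a clade marks its rooted sister SC and the attachment node NA", {
  nodes <- fig_nodes()
  # rows: key "D;E" = the {A,B,C}|{D,E} split; key "C;D;E" = the {A,B} node
  leaves <- LETTERS[1:5]
  series <- fake_series(setdiff(leaves, "C"))
  col <- hetscreen:::restrict_column(nodes, "C", leaves, series,
                                     ref_root = "E")
  stat <- setNames(col$status, nodes$key)
  expect_equal(unname(stat["C;D;E"]), "SC")  # node {A,B}, sister of excluded C
  expect_equal(unname(stat["D;E"]), "NA")    # node {A,B,C} collapses onto it
})

test_that("nodes whose restriction is trivial or engulfed become NA", {
  nodes <- fig_nodes()
  leaves <- LETTERS[1:5]
  # node {A,B,C} restricted by excluding A becomes {B,C}, canonical key "D;E"
  # in the remaining leaf set {B,C,D,E}
  series <- fake_series(setdiff(leaves, "A"), counts = c("D;E" = 40L))
  col <- hetscreen:::restrict_column(nodes, "A", leaves, series,
                                     ref_root = "E")
  stat <- setNames(col$status, nodes$key)
  expect_equal(unname(stat["C;D;E"]), "NA")  # node {A,B} left with one leaf
  expect_equal(unname(stat["D;E"]), "bs")
  expect_equal(col$bs[nodes$key == "D;E"], 40)
})

test_that("a non-monophyletic excluded group yields no SC cell", {
  nodes <- fig_nodes()
  leaves <- LETTERS[1:5]
  series <- fake_series(setdiff(leaves, c("A", "D")))
  col <- hetscreen:::restrict_column(nodes, c("A", "D"), leaves, series,
                                     ref_root = "E")
  expect_false(any(col$status == "SC"))
})

test_that("a restricted bipartition absent from the series scores 0", {
  nodes <- fig_nodes()
  leaves <- LETTERS[1:5]
  # excluding D: node {A,B} keeps {A,B}, canonical key "C;E" among
  # {A,B,C,E}; node {A,B,C} vs {E} becomes trivial
  series <- fake_series(setdiff(leaves, "D"), counts = c("C;E" = 77L))
  col <- hetscreen:::restrict_column(nodes, "D", leaves, series,
                                     ref_root = "E")
  stat <- setNames(col$status, nodes$key)
  expect_equal(unname(stat["D;E"]), "NA")
  expect_equal(col$bs[nodes$key == "C;D;E"], 77)
  series0 <- fake_series(setdiff(leaves, "E"))
  col0 <- hetscreen:::restrict_column(nodes, "E", leaves, series0,
                                      ref_root = "A")
  expect_true(all(col0$bs[col0$status == "bs"] == 0))
})

test_that("the compiled support table has the expected structure", {
  m <- caterpillar_binary()
  g <- read_grouping(m$sample, outgroup = "g6")
  res <- suppress_small_run_warnings(run_het(m, g, B = 40, seed = 8))
  tab <- compile_support_table(res)
  expect_s3_class(tab, "het_support")
  expect_setequal(unique(tab$series), c("full", paste0("g", 1:5)))
  # full column never carries markers
  expect_true(all(tab$marker[tab$series == "full"] == "bs"))
  # perfectly compatible characters: the generating splits are all present
  full <- tab[tab$series == "full", ]
  expect_true("s_g1;s_g2" %in% full$clade)
  expect_true(all(full$bs > 80))
  # each excluded monophyletic group with an internal sister: exactly one SC
  sc_per <- table(factor(tab$series[tab$marker == "SC"],
                         levels = paste0("g", 1:5)))
  expect_true(all(sc_per <= 1))
  # the SC cell sits at the sister of the excluded group: excluding g3,
  # the sister of s_g3 in ((((g1,g2),g3),g4),g5,g6) is the {g1,g2} clade
  sc_g3 <- tab[tab$series == "g3" & tab$marker == "SC", ]
  expect_equal(sc_g3$clade, "s_g1;s_g2")
})

test_that("Tukey fences match the worked example and the brute-force oracle", {
  v <- c(80, 81, 82, 83, 84, 85, 86, 87, 99)
  f <- hetscreen:::tukey_fences(v, 1.5)
  expect_equal(unname(f["q1"]), 82)
  expect_equal(unname(f["q3"]), 86)
  expect_equal(unname(f["upper"]), 92)
  expect_true(99 > f["upper"])
  f3 <- hetscreen:::tukey_fences(v, 3)
  expect_equal(unname(f3["upper"]), 98)   # 99 still an outlier at k = 3
  set.seed(40)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    v <- round(runif(n, 0, 100), 1)
    k <- sample(c(1.5, 3), 1)
    f <- hetscreen:::tukey_fences(v, k)
    o <- oracle_tukey_outliers(v, k)
    expect_equal(unname(f["q1"]), o$q1)
    expect_equal(unname(f["q3"]), o$q3)
    expect_setequal(v[v > f["upper"]], o$upper)
    expect_setequal(v[v < f["lower"]], o$lower)
  }
})

test_that("boxplot outliers respect markers, sample size and filters", {
  # hand-built support table: 8 exclusion columns, one node with an outlier
  mk <- function(node, series, marker, bs, clade, size = 2)
    tibble::tibble(node_id = node, clade = clade, clade_size = size,
                   series = series, marker = marker, bs = bs)
  ser <- paste0("e", 1:8)
  tab <- dplyr::bind_rows(
    mk("N1", "full", "bs", 70, "a;b"),
    mk("N1", ser, "bs", c(70, 71, 72, 73, 74, 75, 76, 99), "a;b"),
    mk("N2", "full", "bs", 50, "a;c"),
    mk("N2", ser, c(rep("bs", 4), rep("NA", 4)),
       c(50, 51, 52, 53, rep(NA, 4)), "a;c"),
    mk("N3", "full", "bs", 90, "c;d"),
    mk("N3", ser, "bs", rep(90, 8), "c;d"))
  grouping <- taxon_grouping(data.frame(
    sample = letters[1:4], group = c("G1", "G1", "G2", "G2")))
  attr(tab, "grouping") <- grouping
  class(tab) <- c("het_support", class(tibble::tibble()))
  expect_warning(o <- boxplot_outliers(tab, k = 1.5), "N2")
  expect_equal(o$outliers$node_id, "N1")
  expect_equal(o$outliers$series, "e8")
  expect_equal(o$outliers$direction, "upper")
  # identical values: IQR 0, nothing flagged
  expect_false("N3" %in% o$outliers$node_id)
  # min_two_groups filter removes the intra-group node a;b (G1 only)
  o2 <- suppressWarnings(boxplot_outliers(tab, k = 1.5,
                                          node_filter = "min_two_groups"))
  expect_false("N1" %in% o2$summary$node_id)
  expect_error(boxplot_outliers(tab, k = 0), "positive")
})

test_that("k = 3 outliers are a subset of k = 1.5 outliers", {
  m <- caterpillar_binary(reps = 3)
  g <- read_grouping(m$sample, outgroup = "g6")
  res <- suppress_small_run_warnings(run_het(m, g, B = 30, seed = 12))
  tab <- compile_support_table(res)
  o15 <- suppressWarnings(boxplot_outliers(tab, k = 1.5))
  o3 <- suppressWarnings(boxplot_outliers(tab, k = 3))
  key <- function(o) paste(o$outliers$node_id, o$outliers$series)
  expect_true(all(key(o3) %in% key(o15)))
})

test_that("custom node queries agree with the support table", {
  m <- caterpillar_binary()
  g <- read_grouping(m$sample, outgroup = "g6")
  res <- suppress_small_run_warnings(run_het(m, g, B = 30, seed = 13))
  tab <- compile_support_table(res)
  q <- query_custom_node(res, c("s_g1", "s_g2"))
  row <- tab[tab$clade == "s_g1;s_g2", ]
  for (i in seq_len(nrow(q))) {
    cell <- row[row$series == q$series[i], ]
    if (nrow(cell) == 1 && q$marker[i] == "bs" && cell$marker == "bs")
      expect_equal(q$bs[i], cell$bs)
  }
  # series excluding part of the leaf set are NA
  expect_equal(q$marker[q$series == "g1"], "NA")
  expect_error(query_custom_node(res, "s_g1"), "at least 2")
  expect_error(query_custom_node(res, c("s_g1", "nope")), "nope")
  p <- autoplot(q, k = 1.5)
  expect_s3_class(p, "ggplot")
})

test_that("the alternative-node registry obeys its bounds", {
  m <- caterpillar_binary()
  g <- read_grouping(m$sample, outgroup = "g6")
  res <- suppress_small_run_warnings(run_het(m, g, B = 30, seed = 14))
  expect_equal(nrow(alt_nodes(res, min_support = 101)), 0)
  # registry entries are never restrictions of full-tree nodes: with ladder
  # data the full-tree splits all reach high support, so no high-support
  # alternative can exist
  expect_equal(nrow(alt_nodes(res, min_support = 80)), 0)
  reg <- alt_nodes(res, min_support = 5)
  tab <- compile_support_table(res)
  if (nrow(reg)) {
    scored <- paste(tab$series, tab$clade)
    expect_false(any(paste(reg$series, reg$clade) %in% scored))
  }
})
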