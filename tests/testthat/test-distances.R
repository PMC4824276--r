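test_that("Nei-Li distance matches hand evaluation and the oracle", {
  m <- toy_binary()
  d <- nei_li_dist(m)
  expect_equal(d$d["a", "a"], 0)
  # a = (1,1,0,1), b = (1,0,1,1): n_xy = 2, n_x = 3, n_y = 3 -> D = 1/3
  expect_equal(d$d["a", "b"], 1 / 3)
  mm <- marker_matrix(m)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d$d[i, j], oracle_nei_li(mm[i, ], mm[j, ]))
  # identical rows -> 0
  m2 <- marker_table(rbind(x = c(1, 0, 1, 1), y = c(1, 0, 1, 1),
                           z = c(0, 1, 0, 0), w = c(1, 1, 1, 0)),
                     dialect = "binary")
  expect_equal(nei_li_dist(m2)$d["x", "y"], 0)
  # all-absent pair -> 0, not NaN
  m3 <- marker_table(rbind(x = c(0, 0), y = c(0, 0), z = c(1, 0),
                           w = c(1, 1)), dialect = "binary")
  expect_equal(nei_li_dist(m3)$d["x", "y"], 0)
})

test_that("missing loci are deleted pairwise", {
  mm <- marker_matrix(toy_binary())
  mm["b", 2] <- NA
  m <- marker_table(mm, dialect = "binary")
  d <- nei_li_dist(m)
  expect_equal(d$n_loci_used["a", "b"], 3)
  expect_equal(d$d["a", "b"], oracle_nei_li(mm["a", c(1, 3, 4)],
                                            mm["b", c(1, 3, 4)]))
  # other pairs unaffected
  expect_equal(d$d["a", "c"], oracle_nei_li(mm["a", ], mm["c", ]))
  # a pair with zero joint loci is an error naming the pair
  mm2 <- marker_matrix(toy_binary())
  mm2["a", 1:2] <- NA; mm2["b", 3:4] <- NA
  expect_error(nei_li_dist(marker_table(mm2, dialect = "binary")),
               "\\(a, b\\)")
})

test_that("allele sharing counts multiset intersections", {
  g <- marker_table(rbind(a = c("AA", "AA", "AG", "CC"),
                          b = c("AC", "CC", "GT", "CC"),
                          c = c("AA", "AC", "AG", "CC"),
                          d = c("CC", "AA", "TT", "AT")),
                    dialect = "snp_nucleotide")
  d <- allele_sharing_dist(g)
  # shared: AA~AC=1, AA~CC=0, AG~GT=1 (tri-allelic), CC~CC=2 -> D = 1 - 4/8
  expect_equal(d$d["a", "b"], 0.5)
  expect_equal(d$d["a", "a"], 0)
  mm <- marker_matrix(g)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d$d[i, j], oracle_allele_sharing(mm[i, ], mm[j, ]),
                 info = paste(i, j))
  # heterozygote shares 2 with itself
  g2 <- marker_table(rbind(a = "AG", b = "AG", c = "AA", d = "GG"),
                     dialect = "snp_nucleotide")
  expect_equal(allele_sharing_dist(g2)$d["a", "b"], 0)
})

test_that("distance matrices are symmetric with zero diagonal and permute consistently", {
  set.seed(3)
  vals <- matrix(sample(c("AA", "AC", "CC", "AG", NA), 120, replace = TRUE,
                        prob = c(rep(0.23, 4), 0.08)),
                 nrow = 6, dimnames = list(paste0("s", 1:6), NULL))
  m <- marker_table(vals, dialect = "snp_nucleotide")
  d <- allele_sharing_dist(m)
  expect_equal(d$d, t(d$d))
  expect_equal(diag(d$d), setNames(rep(0, 6), paste0("s", 1:6)))
  expect_true(all(d$d >= 0 & d$d <= 1))
  perm <- c(4, 2, 6, 1, 3, 5)
  m_p <- marker_table(vals[perm, ], dialect = "snp_nucleotide")
  d_p <- allele_sharing_dist(m_p)
  expect_equal(d_p$d, d$d[perm, perm])
})

test_that("the -log(S) Nei-Li variant is available", {
  m <- toy_binary()
  d <- nei_li_dist(m, log_transform = TRUE)
  expect_equal(d$d["a", "b"], -log(2 / 3))
})

test_that("locus resampling is deterministic and uniform", {
  m <- toy_binary()
  expect_equal(marker_matrix(resample_loci(m, 9)),
               marker_matrix(resample_loci(m, 9)))
  one <- marker_table(matrix(c(1, 0, 1, 0), ncol = 1,
                             dimnames = list(letters[1:4], "L1")),
                      dialect = "binary")
  expect_equal(unname(marker_matrix(resample_loci(one, 4))),
               unname(marker_matrix(one)))
  # expected multiplicity of each column is ~1 under uniform resampling
  counts <- matrix(0, nrow = 2000, ncol = 4)
  for (r in seq_len(2000)) {
    rs <- hetscreen:::with_seed(hetscreen:::derive_seed(77, r),
                                sample.int(4, 4, replace = TRUE))
    counts[r, ] <- tabulate(rs, 4)
  }
  mult <- colMeans(counts)
  se <- sqrt(1 * (1 - 1 / 4) / 2000)   # binomial(4, 1/4) variance = 0.75
  expect_true(all(abs(mult - 1) < 3 * se))
})

test_that("tidy() and TSV export expose the pairwise values", {
  d <- nei_li_dist(toy_binary())
  td <- tidy(d)
  expect_equal(nrow(td), 6)
  expect_equal(td$distance[td$sample1 == "a" & td$sample2 == "b"], 1 / 3)
  f <- withr::local_tempfile()
  write_dist_tsv(d, f)
  back <- read.delim(f)
  expect_equal(back$a, unname(d$d[, "a"]))
})
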