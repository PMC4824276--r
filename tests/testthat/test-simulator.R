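test_that("species-tree models validate their structure", {
  expect_error(one_pop_model(-1), "theta")
  bad <- tibble::tibble(label = c("r", "a", "b", "c"),
                        parent = c(0L, 1L, 2L, 2L),
                        time = c(0.001, 0.002, 0, 0), theta = 1e-4)
  expect_error(species_tree_model(bad, theta = 1e-4), "strictly decrease")
  mod <- nested_species_tree()
  expect_equal(sum(mod$is_tip), 19)           # 18 ingroup taxa + outgroup
  expect_equal(max(mod$time[mod$label == "anc2"]), 2.25e-4)  # ingroup MRCA
  ph <- species_tree_phylo(mod)
  expect_s3_class(ph, "phylo")
  expect_true(ape::is.ultrametric(ph, tol = 1e-12))
  rad <- radiation_species_tree()
  expect_equal(sum(rad$is_tip), 19)
})

test_that("gene trees have the right shape and finite height", {
  mod <- nested_species_tree()
  gts <- simulate_gene_trees(mod, 20, seed = 5)
  H <- sum(mod$n_hap)
  for (gt in gts) {
    expect_equal(length(gt$parent), 2 * H - 1)  # H - 1 coalescences
    expect_equal(sum(gt$parent == 0), 1)        # single root
    expect_true(all(is.finite(gt$time)))
    # parents strictly older than children
    kids <- which(gt$parent > 0)
    expect_true(all(gt$time[gt$parent[kids]] > gt$time[kids] - 1e-15))
  }
  ph <- gene_tree_phylo(gts[[1]])
  expect_equal(ape::Ntip(ph), H)
  # determinism
  gts2 <- simulate_gene_trees(mod, 20, seed = 5)
  expect_equal(gts[[7]]$time, gts2[[7]]$time)
})

test_that("single-population pairwise divergence calibrates to theta", {
  for (theta in c(1e-5, 5e-4)) {
    gts <- simulate_gene_trees(one_pop_model(theta), 4000,
                               seed = round(theta * 1e9))
    dv <- vapply(gts, gene_tree_divergence, numeric(1), 1, 2)
    se <- sd(dv) / sqrt(length(dv))
    expect_lt(abs(mean(dv) - theta), 3 * se)
  }
})

test_that("two-taxon divergence approaches 2*t + theta_ancestral", {
  theta <- 2e-4; t <- 1e-3
  gts <- simulate_gene_trees(two_taxon_model(theta, t), 3000, seed = 17)
  dv <- vapply(gts, gene_tree_divergence, numeric(1), 1, 3)  # across taxa
  se <- sd(dv) / sqrt(length(dv))
  expect_lt(abs(mean(dv) - (2 * t + theta)), 3 * se)
})

test_that("tiny theta makes gene trees mirror the species tree", {
  mod <- nested_species_tree(theta = 1e-12, n_individuals = 1L)
  sp <- species_tree_phylo(mod)
  gts <- simulate_gene_trees(mod, 100, seed = 23)
  match_count <- 0
  sp_keys <- bipart_set(sp)
  for (gt in gts) {
    ph <- gene_tree_phylo(gt)
    # collapse haplotype pairs: with one individual the two haplotypes
    # coalesce instantly; drop one per taxon and compare topologies
    keep <- grep("\\.1$", ph$tip.label, value = TRUE)
    ph1 <- ape::keep.tip(ph, keep)
    ph1$tip.label <- sub(".*_", "", sub("\\.1$", "", ph1$tip.label))
    if (setequal(bipart_set(ph1), sp_keys)) match_count <- match_count + 1
  }
  expect_gte(match_count, 99)
})

test_that("SNP data sets contain only polymorphic loci and obey the budget", {
  mod <- nested_species_tree(theta = 5e-4)
  snp <- simulate_snp_dataset(mod, 80, seed = 31)
  expect_s3_class(snp, "marker_tbl")
  expect_equal(marker_dialect(snp), "snp_nucleotide")
  expect_equal(n_loci(snp), 80)
  mm <- marker_matrix(snp)
  n_alleles <- apply(mm, 2, function(g)
    length(unique(unlist(strsplit(g, "")))))
  expect_true(all(n_alleles >= 2))
  # effectively zero tree length -> no polymorphism, budget error
  flat <- one_pop_model(1e-12, n_individuals = 2L)
  expect_error(simulate_snp_dataset(flat, 10, seed = 1, budget_factor = 20),
               "budget exhausted")
})

test_that("the polymorphic fraction increases with theta", {
  frac <- vapply(c(1e-5, 5e-4), function(th) {
    d <- simulate_snp_dataset(nested_species_tree(theta = th), 40,
                              seed = 41, budget_factor = 1000)
    40 / attr(d, "raw_loci")
  }, numeric(1))
  expect_gt(frac[2], frac[1])
})

test_that("AFLP simulation respects dominance and discards monomorphic loci", {
  mod <- nested_species_tree(theta = 5e-4)
  afl <- simulate_aflp_dataset(mod, 60, seed = 51)
  expect_equal(marker_dialect(afl), "binary")
  mm <- marker_matrix(afl)
  expect_true(all(colSums(mm) > 0 & colSums(mm) < nrow(mm)))
  # per-haplotype band-loss probability on a branch of length b is about
  # 1 - exp(-10b): check via a two-haplotype population with a long stem
  theta <- 1e-6; t <- 5e-3
  mod2 <- two_taxon_model(theta, t, n_individuals = 2L)
  # bands per individual = OR of its two haplotypes; with theta tiny the two
  # haplotypes are identical, so individual band loss ~ haplotype band loss
  afl2 <- simulate_aflp_dataset(mod2, 150, seed = 52, budget_factor = 50)
  mm2 <- marker_matrix(afl2)
  # among polymorphic loci, expected pattern: exactly one side lost the band
  expect_true(all(rowSums(mm2) > 0))
})

test_that("hybrid data sets merge two equal-contribution simulations", {
  mod <- nested_species_tree(theta = 5e-4)
  hyb <- hybrid_spec("l", "s", 1e-5)
  expect_warning(sim <- make_hybrid_dataset(mod, hyb, 81, seed = 61,
                                            marker = "snp"),
                 "rounded up")
  expect_equal(n_loci(sim$data), 82)
  expect_true("hyb1_hyb" %in% sim$data$sample)
  expect_equal(sim$truth$hybrid_group, "hyb")
  expect_equal(sim$truth$parents, list(a = "l", b = "s"))
  # the hybrid is about equidistant from the two parents
  d <- allele_sharing_dist(sim$data)$d
  hybs <- grep("_hyb$", rownames(d), value = TRUE)
  dl <- mean(d[hybs, grep("^l\\d", colnames(d))])
  ds <- mean(d[hybs, grep("^s\\d", colnames(d))])
  diffs <- replicate(6, {
    s <- sample.int(1e6, 1)
    sm <- make_hybrid_dataset(mod, hyb, 120, seed = s, marker = "snp")
    dd <- allele_sharing_dist(sm$data)$d
    h <- grep("_hyb$", rownames(dd), value = TRUE)
    mean(dd[h, grep("^l\\d", colnames(dd))]) -
      mean(dd[h, grep("^s\\d", colnames(dd))])
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-8)
  # grafting outside the parental branch is rejected
  expect_error(graft_hybrid(mod, "l", 5e-4), "outside the branch")
})

test_that("an instant hybrid origin gives a 50/50 parental mosaic", {
  mod <- nested_species_tree(theta = 1e-9, n_individuals = 1L)
  hyb <- hybrid_spec("l", "s", 1e-9 / 2)
  sim <- suppressWarnings(make_hybrid_dataset(mod, hyb, 60, seed = 71,
                                              marker = "snp",
                                              budget_factor = 2000))
  mm <- marker_matrix(sim$data)
  h <- mm["hyb1_hyb", ]
  agree_l <- mean(h == mm["l1_l", ])
  agree_s <- mean(h == mm["s1_s", ])
  # half the loci identical to each parent (the other half mostly differs
  # because the markers are ascertained to be polymorphic)
  expect_gt(agree_l, 0.45)
  expect_gt(agree_s, 0.45)
})
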