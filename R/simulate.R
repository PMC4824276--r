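# Coalescent simulation of SNP and AFLP data sets, including planted hybrids.

model_args <- function(model) {
  list(parent = model$parent, tau = model$time, theta = model$theta,
       order = model_order(model), n_hap = model$n_hap)
}

# sample ids "<taxon><i>_<taxon>" so the default suffix grouping recovers the
# taxon; haplotypes arrive grouped per tip in processing order, consecutive
# pairs forming diploid individuals
model_samples <- function(model) {
  ord <- model_order(model)
  tips <- ord[model$is_tip[ord]]
  unlist(lapply(tips, function(v)
    paste0(model$label[v], seq_len(model$n_hap[v] / 2L), "_", model$label[v])))
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Within each species-tree branch, lineages coalesce pairwise at rate
#' `2/theta` per unit time; lineages surviving at the top of a branch enter
#' the parent branch, and coalescence continues above the root until a single
#' lineage remains. The expected within-population pairwise coalescent time is
#' `theta/2`, i.e. an expected pairwise divergence (sum of the two branch
#' paths) of `theta`.
#'
#' @param model a `species_tree_model`.
#' @param n_trees number of independent gene trees.
#' @param seed integer seed.
#' @return a list of gene trees; each is a list with `parent` (1-based gene
#'   node parents, 0 for the root), `time` (node times), and `tip_label`
#'   (haplotype labels `<taxon><individual>_<taxon>.<1|2>`). Tips are the
#'   first `length(tip_label)` nodes.
#' @export
simulate_gene_trees <- function(model, n_trees, seed) {
  stopifnot(inherits(model, "species_tree_model"))
  res <- with_seed(seed, do.call(msc_gene_trees,
                                 c(model_args(model), list(n_loci = n_trees))))
  samples <- model_samples(model)
  hap_labels <- paste0(rep(samples, each = 2L), ".", 1:2)
  lapply(seq_len(n_trees), function(l) {
    list(parent = res$gparent[, l], time = res$gtime[, l],
         tip_label = hap_labels)
  })
}

#' @rdname simulate_gene_trees
#' @param tree one gene tree from `simulate_gene_trees()`.
#' @return `gene_tree_phylo()`: the [ape::phylo] version of one gene tree.
#' @export
gene_tree_phylo <- function(tree) {
  G <- length(tree$parent)
  H <- (G + 1L) / 2L
  renum <- integer(G)
  renum[seq_len(H)] <- seq_len(H)
  internals <- c(G, (H + 1L):(G - 1L))  # root (last created) first
  if (H + 1L > G - 1L) internals <- G
  renum[internals] <- H + seq_along(internals)
  has_parent <- tree$parent > 0L
  edge <- cbind(renum[tree$parent[has_parent]], renum[which(has_parent)])
  len <- tree$time[tree$parent[has_parent]] - tree$time[which(has_parent)]
  tr <- list(edge = edge, tip.label = tree$tip_label,
             edge.length = len, Nnode = length(internals))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' @rdname simulate_gene_trees
#' @param h1,h2 1-based haplotype (tip) indices.
#' @return `gene_tree_divergence()`: the branch-path length between two
#'   haplotypes (twice their coalescent time).
#' @export
gene_tree_divergence <- function(tree, h1, h2) {
  anc <- function(h) {
    path <- h
    while (tree$parent[h] > 0L) { h <- tree$parent[h]; path <- c(path, h) }
    path
  }
  a1 <- anc(h1); a2 <- anc(h2)
  m <- min(intersect(a1, a2))
  2 * tree$time[m]
}

#' Simulate a SNP data set under the multispecies coalescent
#'
#' One gene tree per raw locus; a single site evolves under Jukes-Cantor from
#' a uniform-random ancestral base (loci recombine freely). Loci monomorphic
#' across all sampled haplotypes are discarded; simulation continues until
#' `n_loci` polymorphic loci are collected or the raw-locus budget is
#' exhausted. The two haplotypes of each diploid individual are combined into
#' an unordered nucleotide genotype.
#'
#' @param model a `species_tree_model`.
#' @param n_loci number of polymorphic loci required.
#' @param seed integer seed.
#' @param budget_factor raw-locus budget as a multiple of `n_loci`.
#' @return a `marker_tbl` in the `snp_nucleotide` dialect with attribute
#'   `raw_loci` (raw loci simulated).
#' @export
simulate_snp_dataset <- function(model, n_loci, seed, budget_factor = 200) {
  stopifnot(inherits(model, "species_tree_model"))
  res <- with_seed(seed, do.call(msc_snp, c(
    model_args(model),
    list(target_poly = as.integer(n_loci),
         max_raw = as.integer(ceiling(budget_factor * n_loci))))))
  if (res$n_poly < n_loci)
    stop("raw-locus budget exhausted: ", res$n_poly, " polymorphic loci from ",
         res$raw_used, " raw loci (requested ", n_loci, ")")
  bases <- c("A", "C", "G", "T")
  al <- matrix(bases[res$alleles + 1L], nrow = nrow(res$alleles))
  H <- nrow(al)
  a1 <- al[seq(1, H, by = 2), , drop = FALSE]
  a2 <- al[seq(2, H, by = 2), , drop = FALSE]
  geno <- matrix(paste0(pmin(a1, a2), pmax(a1, a2)), nrow = nrow(a1))
  rownames(geno) <- model_samples(model)
  colnames(geno) <- paste0("L", seq_len(ncol(geno)))
  out <- marker_table(geno, "snp_nucleotide")
  attr(out, "raw_loci") <- res$raw_used
  out
}

#' Simulate a dominant AFLP data set under the multispecies coalescent
#'
#' Each locus carries `n_sites` restriction-recognition positions evolving
#' under Jukes-Cantor on the locus' gene tree; a haplotype carries the band
#' only if all positions still match the ancestral recognition state
#' (back-mutation can restore it). A diploid individual scores 1 if at least
#' one of its haplotypes carries the band (dominance). Loci monomorphic
#' across individuals are discarded.
#'
#' @inheritParams simulate_snp_dataset
#' @param n_sites recognition positions per locus (10 = two 5-bp restriction
#'   sites).
#' @return a `marker_tbl` in the `binary` dialect with attribute `raw_loci`.
#' @export
simulate_aflp_dataset <- function(model, n_loci, seed, budget_factor = 200,
                                  n_sites = 10L) {
  stopifnot(inherits(model, "species_tree_model"))
  res <- with_seed(seed, do.call(msc_aflp, c(
    model_args(model),
    list(target_poly = as.integer(n_loci),
         max_raw = as.integer(ceiling(budget_factor * n_loci)),
         n_sites = as.integer(n_sites)))))
  if (res$n_poly < n_loci)
    stop("raw-locus budget exhausted: ", res$n_poly, " polymorphic loci from ",
         res$raw_used, " raw loci (requested ", n_loci, ")")
  bands <- res$bands
  rownames(bands) <- model_samples(model)
  colnames(bands) <- paste0("L", seq_len(ncol(bands)))
  out <- marker_table(bands, "binary")
  attr(out, "raw_loci") <- res$raw_used
  out
}

#' Simulate a data set containing a planted hybrid taxon
#'
#' Two parallel simulations are run: one with the hybrid taxon branching off
#' the first parental lineage at `tau_h`, one with it branching off the
#' second, each contributing half of the requested loci. Concatenating the two
#' marker matrices makes the hybrid taxon's genotype a 50/50 mosaic of
#' unlinked markers inherited from the two parents, while every other taxon is
#' present in both halves.
#'
#' @param model a `species_tree_model` (without the hybrid).
#' @param hybrid a [hybrid_spec()].
#' @param n_loci total polymorphic loci (rounded up to an even number).
#' @param seed integer seed; the two half-simulations use seeds derived from
#'   it.
#' @param marker `"snp"` or `"aflp"`.
#' @param budget_factor raw-locus budget multiple, per half.
#' @return a list with `data` (the merged `marker_tbl`) and `truth` (a list
#'   with the hybrid group label and the taxon labels of the two parental
#'   lineages, for [classify_signals()]).
#' @export
make_hybrid_dataset <- function(model, hybrid, n_loci, seed,
                                marker = c("snp", "aflp"),
                                budget_factor = 200) {
  stopifnot(inherits(model, "species_tree_model"),
            inherits(hybrid, "hybrid_spec"))
  marker <- match.arg(marker)
  if (n_loci %% 2L != 0L) {
    n_loci <- n_loci + 1L
    warning("odd locus count rounded up to ", n_loci)
  }
  m_a <- graft_hybrid(model, hybrid$parent_a, hybrid$tau_h, hybrid$label)
  m_b <- graft_hybrid(model, hybrid$parent_b, hybrid$tau_h, hybrid$label)
  simulate <- if (marker == "snp") simulate_snp_dataset else simulate_aflp_dataset
  half <- n_loci %/% 2L
  d_a <- simulate(m_a, half, derive_seed(seed, "hybrid_half_a"), budget_factor)
  d_b <- simulate(m_b, half, derive_seed(seed, "hybrid_half_b"), budget_factor)
  ma <- marker_matrix(d_a)
  mb <- marker_matrix(d_b)[rownames(marker_matrix(d_a)), , drop = FALSE]
  colnames(mb) <- paste0("L", half + seq_len(half))
  merged <- marker_table(cbind(ma, mb), marker_dialect(d_a))
  truth <- list(hybrid_group = hybrid$label,
                parents = list(a = hybrid$parent_a, b = hybrid$parent_b),
                tau_h = hybrid$tau_h, marker = marker)
  list(data = merged, truth = truth)
}
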