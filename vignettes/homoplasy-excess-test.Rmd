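---
title: "Screening multilocus phylogenies for hybrid taxa with hetscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening multilocus phylogenies for hybrid taxa with hetscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetscreen)
```

## The homoplasy excess test

A hybrid taxon carries a mosaic of alleles inherited from its two parental
lineages. In a multilocus distance tree it is drawn to a position intermediate
between the parents, and the loci that tie it alternately to one parent or the
other act as homoplasy: they erode bootstrap support for the clades containing
the parents. The homoplasy excess test (HET) turns this around. The analysis is
repeated on *taxon-jackknife* data sets, each excluding one taxon (a species,
population, or any user-defined group of samples) at a time. If excluding one
particular taxon raises bootstrap support for some node far more than excluding
any other taxon does, the excluded taxon behaves like a hybrid and the affected
node points at a parental lineage.

Concretely, `run_het()`:

1. computes pairwise genetic distances — the Nei–Li (Dice) distance
   $D = 1 - 2 n_{xy} / (n_x + n_y)$ for dominant binary markers (AFLP/RFLP
   band presence), or the allele-sharing distance
   $D = 1 - \frac{1}{2L}\sum_\ell s_\ell$ for co-dominant SNP genotypes, where
   $s_\ell \in \{0,1,2\}$ is the number of alleles the two unordered diploid
   genotypes share at locus $\ell$, counted with multiplicity;
2. estimates a neighbour-joining tree and assesses node support by
   bootstrapping across loci ($B$ resamples of the marker columns);
3. repeats both steps for every exclusion experiment;
4. compiles, for every internal node of the full tree, the support of its
   restricted bipartition in every jackknife series (`compile_support_table()`);
5. summarises each node's support distribution with Tukey hinges and flags
   values beyond $k \times \mathrm{IQR}$ from the hinges as outliers
   (`boxplot_outliers()`).

Upper outliers are candidate hybrid signals; interpretation is deliberately
left to the user — the pattern of topology changes, parent-exclusion effects
and maximum-but-not-outlier support values matters as much as any single
outlier, and the screen is exploratory, not a test with a controlled error
rate.

## Support carryover and the table semantics

Removing a taxon always inflates support for its sister clade, because the
characters that used to pull the excluded taxon towards its sister now support
the sister node undiluted. This *support carryover* is independent of
hybridization, so the cell for the sister of the excluded clade is marked `SC`
and excluded from the node's boxplot sample. Sisterhood is read off the full
tree rooted at the outgroup when one is given; without an outgroup the tree is
oriented away from a fixed reference sample, and the `SC` call for nodes
adjacent to the exclusion should be interpreted with care. A group that is not
monophyletic in the full tree has no sister, and its column contains no `SC`
cell.

Other cells can become meaningless after an exclusion: a node whose leaf set
shrinks below two samples, turns into a trivial bipartition of the remaining
leaf set, or collapses onto another node's restriction is marked `NA`. When two
full-tree nodes restrict to the same bipartition, the smaller clade keeps the
score and the larger (attachment-side) node is `NA`, so no bipartition is
counted twice in one column. A restricted bipartition that simply never occurs
among a series' bootstrap trees scores 0 — a real observation, and the way
topology-breaking hybrids show up as *lower* outliers.

`query_custom_node()` scores any user-defined leaf set across all series, and
`alt_nodes()` collects bipartitions that reach appreciable support in some
jackknife series without being restrictions of any full-tree node: both matter
when the hybrid disrupts the monophyly of a parent in the full tree, so that
the "true" node only materialises once the hybrid is gone.

## Outlier detection choices

Quartiles are Tukey hinges (`fivenum()`'s fourths), not interpolated
quantiles: the published applications of the test follow Tukey's boxplot, and
hinges on small samples (one value per exclusion experiment, typically 7–50)
are the convention the reported `k = 1.5` and `k = 3` fences assume. Outliers
must lie strictly beyond a fence. Nodes with fewer than five numeric cells are
skipped with a warning — hinges on four values are not meaningful. The
`min_two_groups` node filter restricts reporting to nodes that join at least
two groups; intra-group nodes attract upper outliers whenever a closely
related group is removed, and most published analyses ignore them. The filter
is off by default so nothing is hidden.

`classify_signals()` scores a run against a simulation truth record. A
maximum-but-not-outlier signal requires the hybrid-exclusion cell to be the
*unique* row maximum: with many cells at 100 a shared maximum carries no
information. A hybrid-exclusion outlier at a node containing descendants of
both parental lineages counts once per lineage, mirroring how per-lineage
signals are tallied in the evaluation tables.

## The coalescent simulator

`simulate_snp_dataset()` and `simulate_aflp_dataset()` draw gene trees under
the multispecies coalescent on a species tree whose node times $\tau$ are in
expected substitutions per site and whose branches carry
$\theta = 4N_e\mu$: within a branch, $k$ lineages coalesce at total rate
$k(k-1)/\theta$ per unit $\tau$, survivors enter the parent branch, and
coalescence continues above the root. Mutations fall on the gene tree as a
Poisson process with rate 1 per unit branch length and resolve under
Jukes–Cantor, so back-mutation is possible. A SNP locus is a single site
(loci recombine freely); loci monomorphic across all sampled haplotypes are
discarded and simulation continues until the requested number of polymorphic
loci is reached or a raw-locus budget (default 200 times the request) runs
out. An AFLP locus carries ten restriction-recognition positions; a haplotype
retains the band only while all ten match the ancestral state, and a diploid
shows the band if either haplotype retains it (dominance). AFLP loci
monomorphic across individuals are discarded.

A hybrid taxon is planted by running two half-simulations — the hybrid tip
grafted onto one parental lineage at the hybridization time $\tau_H$, then
onto the other — and concatenating the two marker matrices, so the hybrid's
genome is a 50/50 mosaic of unlinked markers from the two parents while every
other taxon is unaffected. This models a single instantaneous hybrid origin;
continuous gene flow, unequal admixture and within-locus recombination are out
of scope.

The built-in `nested_species_tree()` is an 18-ingroup-taxon, two-diploids-per-
taxon topology with the ingroup MRCA at $\tau = 2.25\times10^{-4}$ and the
most recent splits at $10^{-5}$, built so that the three hybridization
scenarios used throughout the simulation studies fit inside it: a recent
hybrid between the lineages of taxa *l* and *s*, a hybrid between the
lineage ancestral to the (r,q) cherry and taxon *k*
($\tau_H = 2.5\times10^{-5}$), and an ancient hybrid between the (r,q) and
(l,m,n) lineages ($\tau_H = 3.7\times10^{-5}$). Only the root, the most
recent splits and the hybridization times are externally fixed; the remaining
internal node times are spread by depth between those anchors, and the
outgroup divergence is set to $4.5\times10^{-4}$ (about twice the ingroup
root — deep enough to root reliably, close enough to remain alignable).
`radiation_species_tree()` places 17 of the 18 ingroup splits almost
simultaneously ($\tau$ between $5\times10^{-5}$ and $5.8\times10^{-5}$) to
emulate a hard radiation. $\theta$ is uniform across branches by default (a
per-branch column is accepted), since lineage-specific population sizes are a
refinement the screening questions here do not need.

What the simulator does *not* emulate about real data: ascertainment beyond
the polymorphism filter, genotyping error and allele dropout, linkage,
migration after the hybridization event, and AFLP homoplasy from co-migrating
fragments. Tests passing on simulated data therefore validate the machinery
and its statistical behaviour under the model, not robustness to these
artefacts.

## Numerical and design notes

* **Distances** use pairwise deletion: every pair is scored over the loci
  observed in both samples, and a bootstrap replicate that leaves a pair with
  no jointly observed locus is redrawn under the next derived seed (at most
  100 times), keeping $B$ constant. Shared band absence never counts as
  similarity (absence of an AFLP band is not homologous); a pair of all-absent
  profiles gets distance 0 rather than 0/0. The $-\log S$ Nei–Li variant is
  available behind a flag.
* **Trees** come from `ape::nj()`; negative branch lengths are kept (a
  display clamp is available). Support lives on unrooted bipartitions;
  outgroup rooting affects display and the orientation of the clade lattice
  only.
* **Determinism**: every series and every bootstrap replicate draws its seed
  from the master seed by hashing, so results are bit-identical across
  serial and parallel execution and any single series can be reproduced in
  isolation.
* **Performance**: per-pair per-locus sharing counts are precomputed once, so
  a bootstrap replicate is two matrix–vector products; gene-tree simulation
  and mutation dropping are compiled code. A full screen at the default study
  scale (40 samples, ~1300 SNP loci, 20 series, $B=200$) runs in well under a
  minute; the test suite's largest check (ten such screens) stays within a
  few minutes.
* **Problem sizes in the tests**: the NJ consistency check uses 200 random
  additive matrices of 5–8 leaves; the outlier engine is checked against a
  brute-force oracle on 1000 random rows; coalescent calibration uses 10,000
  two-haplotype gene trees per $\theta$ regime; planted-hybrid recovery uses
  ten independent data sets at $\theta = 5\times10^{-4}$, $\tau_H = 10^{-5}$,
  ~1300 SNP loci and $B = 200$; the false-positive/support relationship is
  measured on a six-run grid crossing $\theta \in \{10^{-5},
  5\times10^{-4}\}$ with 300–4000 loci.

## Known limitations

The screen inherits the test's documented failure modes: false positives
arise from heterogeneous shared ancestral polymorphism (more of them the
weaker the tree), and false negatives from trees so well supported that there
is no room for an excess, from support carryover masking a hybrid placed
sister to its parent, and from hybrids that change the tree topology outright
(these surface as lower outliers or only via `alt_nodes()`). Outlier counts
are therefore reported, never turned into an automated hybrid verdict.
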