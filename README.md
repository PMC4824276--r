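# hetscreen

Taxon-jackknife screening for hybrid taxa in multilocus nuclear phylogenies —
an R implementation of the homoplasy excess test (HET), together with a
multispecies-coalescent simulator for SNP and dominant AFLP markers with
planted hybrid taxa, and an evaluation harness that scores outlier signals
against the simulated truth.

## Who this is for

Systematists and population geneticists with a samples-by-loci marker matrix
(AFLP/RFLP presence–absence, SNP genotypes as nucleotide pairs such as
`AG GG TC AA`, or 0/1/2 genotype codes) who suspect that one of their taxa is
of hybrid origin. The HET needs no phasing, no model-based tree inference and
no large per-taxon sample sizes — only enough taxa (ideally ≥ 7) for outlier
statistics across exclusion experiments to make sense.

## The test

A hybrid taxon's genome is a mosaic of its parents' alleles. In a
neighbour-joining tree this mosaic acts as homoplasy that depresses bootstrap
support for the clades containing the parents. The HET therefore re-runs the
bootstrap analysis once per *taxon-jackknife* data set — each excluding one
taxon (group of samples) at a time — and compiles, for every internal node of
the full tree, the support values observed across all exclusions:

* distances: Nei–Li `D = 1 − 2·n_xy/(n_x + n_y)` for binary markers,
  allele-sharing `D = 1 − Σ s_ℓ / (2L)` for diploid genotypes
  (`s_ℓ` = alleles shared at locus ℓ, counted with multiplicity), both with
  pairwise deletion of missing loci;
* trees: neighbour-joining, support by bootstrapping across loci;
* accounting: the sister of an excluded clade is marked `SC` (support
  carryover — its gain is expected regardless of hybridization) and nodes
  that collapse after the exclusion are `NA`; both are excluded from the
  statistics;
* detection: per node, Tukey hinges over the jackknife support values;
  values beyond `k × IQR` from the hinges (`k` = 1.5 or 3) are outliers.
  An upper outlier caused by excluding taxon H at a node containing lineage P
  reads: *H behaves like a hybrid, P like a parental lineage*.

## Worked example

Simulate a data set with a known recent hybrid (taxon `hyb`, parents `l` and
`s`) on the built-in 18-ingroup-taxon species tree, then screen it:

```r
library(hetscreen)

model    <- nested_species_tree(theta = 5e-4)        # 19 taxa, 2 diploids each
hyb      <- hybrid_spec("l", "s", tau_h = 1e-5)      # recent hybrid l x s
sim      <- make_hybrid_dataset(model, hyb, 300, seed = 42, marker = "snp")
grouping <- read_grouping(sim$data$sample, outgroup = "out")

res <- run_het(sim$data, grouping, B = 200, seed = 42)
res
#> Homoplasy excess test result
#>   samples: 40 (snp_nucleotide, allele_sharing distance)
#>   bootstrap replicates: 200 per series
#>   series: full + 19 exclusions

tab <- compile_support_table(res)       # nodes x exclusions, with SC/NA cells
out <- boxplot_outliers(tab, k = 1.5)
dplyr::filter(out$outliers, direction == "upper")
#> # A tibble: 24 x 6
#>    node_id clade             direction series    bs full_bs
#>    <chr>   <chr>             <chr>     <chr>  <dbl>   <dbl>
#>  1 N02     c2_c;f2_f         upper     m       46.5    37.5
#>  2 N04     g1_g;g2_g         upper     j       80      74.5
#>  3 N06     hyb1_hyb;hyb2_hyb upper     s       82.5    55.5
#>  4 N07     j1_j;j2_j         upper     g       81.5    67
#>  ...
```

Row 3 is a textbook parent-exclusion signal: removing parent `s` lifts support
for the hybrid's own node from 55.5% to 82.5%. Scoring the whole run against
the simulation truth:

```r
classify_signals(out, sim$truth)
#> # A tibble: 1 x 8
#>   hybrid_outliers_k1.5 hybrid_outliers_k3 max_bs_not_outlier ...
#> 1                    2                  0                  0
```

Two upper outliers caused by excluding the hybrid sit at nodes containing a
parental lineage (true positives); the remaining upper outliers — exclusions
of non-hybrid taxa — are the false-positive background that makes
interpretation of real data a matter of judgement, not automation. Per-node
support across every series, including nodes absent from the full tree:

```r
query_custom_node(res, c("hyb1_hyb", "hyb2_hyb"))
#> # A tibble: 20 x 3
#>   series marker    bs
#> 1 full   bs      55.5
#> 2 r      bs      55.5
#> 3 q      bs      51.5
#> 4 k      bs      55.5
#> 5 s      bs      82.5
#> ...
```

`write_het_outputs(res, "het_out/")` writes newick trees for every series
(support as node labels), the wide support table with literal `SC`/`NA`
markers, the outlier and alternative-node tables (TSV) and a boxplot panel
(PDF). A thin command-line front end covering simulate/run/evaluate/query is
installed at `inst/cli/het`.

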