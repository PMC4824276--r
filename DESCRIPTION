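Package: hetscreen
Title: Taxon-Jackknife Homoplasy Excess Screening for Hybrid Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tree-based screening for hybrid taxa in multilocus nuclear data
    sets (AFLP presence/absence and SNP genotype matrices) via the homoplasy
    excess test: neighbour-joining trees with locus bootstrap are computed for
    the full data set and for taxon-jackknife data sets that each exclude one
    taxon, bootstrap support for every node of the full tree is compiled across
    exclusion experiments with support-carryover accounting, and excess
    increases in node support are flagged as Tukey boxplot outliers pointing at
    candidate hybrids and their parents. Includes a multispecies-coalescent
    simulator for SNP and dominant AFLP markers with planted hybrid taxa, and
    an evaluation harness that scores true- and false-positive outlier signals
    against the simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
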