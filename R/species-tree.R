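#' Species-tree models for coalescent simulation
#'
#' A species-tree model is a rooted tree whose nodes carry divergence times
#' `tau` (expected substitutions per site; tips at 0, parents strictly older
#' than children) and whose branches carry the population-mutation parameter
#' `theta = 4*Ne*mu` (the branch above each node; the root's value is the
#' ancestral population extending beyond the root). Each tip taxon is sampled
#' with `n_individuals` diploid individuals, i.e. `2 * n_individuals`
#' haplotypes.
#'
#' `species_tree_model()` builds a model from an ultrametric [ape::phylo]
#' tree (branch lengths in expected substitutions/site) or from a node table
#' with columns `label`, `parent` (integer index, 0 for the root), `time` and
#' optionally `theta`. `nested_species_tree()` is the built-in 18-ingroup +
#' outgroup topology used throughout the simulation studies (ingroup root at
#' tau = 0.000225, most recent splits at 0.00001); `radiation_species_tree()`
#' is an 18-taxon near-simultaneous radiation (splits between 0.00005 and
#' 0.000058).
#'
#' @param x an ultrametric [ape::phylo] or a node data frame (see Details).
#' @param theta population parameter; a single value is applied to every
#'   branch.
#' @param n_individuals diploid individuals sampled per taxon.
#' @return an object of class `species_tree_model`.
#' @export
species_tree_model <- function(x, theta, n_individuals = 2L) {
  if (inherits(x, "phylo")) {
    depth <- ape::node.depth.edgelength(x)
    age <- max(depth) - depth
    ntip <- length(x$tip.label)
    M <- ntip + x$Nnode
    parent <- integer(M)
    parent[x$edge[, 2]] <- x$edge[, 1]
    label <- c(x$tip.label, paste0("anc", seq_len(x$Nnode)))
    if (any(age[seq_len(ntip)] > 1e-12))
      stop("species tree must be ultrametric (all tips at time 0)")
    age[seq_len(ntip)] <- 0
    tbl <- tibble::tibble(label = label, parent = parent, time = age)
  } else {
    tbl <- tibble::as_tibble(x)
    stopifnot(all(c("label", "parent", "time") %in% names(tbl)))
  }
  if (!"theta" %in% names(tbl)) tbl$theta <- theta
  new_species_tree(tbl, n_individuals)
}

new_species_tree <- function(tbl, n_individuals) {
  M <- nrow(tbl)
  is_tip <- !(seq_len(M) %in% tbl$parent)
  if (any(tbl$time[is_tip] != 0)) stop("tip taxa must be at time 0")
  if (any(tbl$theta <= 0)) stop("theta must be positive")
  root <- which(tbl$parent == 0L)
  if (length(root) != 1L) stop("exactly one root required")
  for (i in seq_len(M)) {
    p <- tbl$parent[i]
    if (p > 0L && tbl$time[p] <= tbl$time[i])
      stop("node times must strictly decrease towards the tips (node '",
           tbl$label[i], "')")
  }
  if (anyDuplicated(tbl$label[is_tip]))
    stop("duplicated tip labels")
  structure(list(label = tbl$label, parent = as.integer(tbl$parent),
                 time = tbl$time, theta = tbl$theta,
                 is_tip = is_tip,
                 n_hap = ifelse(is_tip, 2L * n_individuals, 0L),
                 n_individuals = as.integer(n_individuals)),
            class = "species_tree_model")
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat("Species-tree model: ", sum(x$is_tip), " taxa, ",
      x$n_individuals, " diploid individuals each\n",
      "  root time ", format(max(x$time)), ", theta ",
      paste(format(unique(x$theta)), collapse = "/"), "\n", sep = "")
  invisible(x)
}

# children-before-parents processing order (times strictly decrease towards
# tips, so sorting by time works; ties among contemporaneous tips are fine)
model_order <- function(model) order(model$time)

#' @rdname species_tree_model
#' @param model a `species_tree_model`.
#' @return `species_tree_phylo()`: the [ape::phylo] rendering of the model
#'   (branch lengths in expected substitutions/site).
#' @export
species_tree_phylo <- function(model) {
  M <- length(model$label)
  tips <- which(model$is_tip)
  ntip <- length(tips)
  renum <- integer(M)
  renum[tips] <- seq_len(ntip)
  internals <- which(!model$is_tip)
  root <- which(model$parent == 0L)
  internals <- c(root, setdiff(internals, root))
  renum[internals] <- ntip + seq_along(internals)
  has_parent <- model$parent > 0L
  edge <- cbind(renum[model$parent[has_parent]], renum[which(has_parent)])
  len <- model$time[model$parent[has_parent]] - model$time[has_parent]
  tr <- list(edge = edge, tip.label = model$label[tips],
             edge.length = len, Nnode = length(internals))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

# tip labels under each node
model_descendants <- function(model, node) {
  M <- length(model$label)
  desc <- node
  repeat {
    kids <- which(model$parent %in% desc)
    new <- setdiff(kids, desc)
    if (!length(new)) break
    desc <- c(desc, new)
  }
  model$label[intersect(desc, which(model$is_tip))]
}

# node whose subtree's tip set equals `taxa` (a tip for a single label)
model_mrca <- function(model, taxa) {
  tips <- match(taxa, model$label)
  if (anyNA(tips)) stop("unknown taxa: ",
                        paste(taxa[is.na(tips)], collapse = ", "))
  if (length(tips) == 1L) return(tips)
  cand <- which(!model$is_tip)
  sizes <- vapply(cand, function(v) length(model_descendants(model, v)),
                  integer(1))
  cand <- cand[order(sizes)]
  for (v in cand) {
    d <- model_descendants(model, v)
    if (all(taxa %in% d)) {
      if (!setequal(d, taxa))
        warning("taxa ", paste(taxa, collapse = ","),
                " are not monophyletic; using their MRCA")
      return(v)
    }
  }
  stop("no MRCA found")
}

#' Graft a hybrid taxon onto a parental lineage
#'
#' Attaches a new tip to the branch ancestral to `parents` (a tip label or
#' the labels whose MRCA defines the lineage) at time `tau_h`, which must lie
#' within that branch. Used twice - once per parental lineage - to build the
#' two half-simulations of a hybrid data set.
#'
#' @param model a `species_tree_model`.
#' @param parents character vector of tip labels defining the parental
#'   lineage.
#' @param tau_h hybrid origin time (expected substitutions/site).
#' @param label tip label of the hybrid taxon.
#' @export
graft_hybrid <- function(model, parents, tau_h, label = "hyb") {
  v <- model_mrca(model, parents)
  p <- model$parent[v]
  upper <- if (p == 0L) Inf else model$time[p]
  if (!(tau_h > model$time[v] && tau_h < upper))
    stop(sprintf("tau_h = %g outside the branch above '%s' (%g, %g)",
                 tau_h, paste(parents, collapse = ","), model$time[v], upper))
  M <- length(model$label)
  w <- M + 1L; h <- M + 2L
  out <- list(
    label = c(model$label, paste0(label, "_anc"), label),
    parent = c(model$parent, p, w),
    time = c(model$time, tau_h, 0),
    theta = c(model$theta, model$theta[v], model$theta[v]),
    is_tip = c(model$is_tip, FALSE, TRUE),
    n_hap = c(model$n_hap, 0L, 2L * model$n_individuals),
    n_individuals = model$n_individuals)
  out$parent[v] <- w
  structure(out, class = "species_tree_model")
}

node_spec <- function(time, ...) list(time = time, children = list(...))

flatten_spec <- function(spec) {
  label <- character(0); parent <- integer(0); time <- numeric(0)
  add <- function(node, par) {
    if (is.character(node)) {
      label <<- c(label, node); parent <<- c(parent, par); time <<- c(time, 0)
      return(invisible())
    }
    label <<- c(label, paste0("anc", length(label) + 1L))
    parent <<- c(parent, par); time <<- c(time, node$time)
    me <- length(label)
    for (ch in node$children) add(ch, me)
  }
  add(spec, 0L)
  tibble::tibble(label = label, parent = parent, time = time)
}

#' @rdname species_tree_model
#' @param outgroup_time divergence time of the outgroup from the ingroup.
#' @export
nested_species_tree <- function(theta = 5e-4, n_individuals = 2L,
                                outgroup_time = 4.5e-4) {
  nd <- node_spec
  ingroup <- nd(2.25e-4,
    nd(1.8e-4,
       nd(9e-5,
          nd(5e-5, nd(1e-5, "r", "q"), "k"),
          nd(6e-5, "s", nd(3e-5, "l", nd(1e-5, "m", "n")))),
       nd(7e-5,
          nd(4e-5, nd(1e-5, "c", "d"), nd(1.5e-5, "e", "f")),
          nd(3e-5, "g", nd(1e-5, "h", "j")))),
    nd(5e-5, nd(1e-5, "w", "x"), nd(1.2e-5, "y", "o")))
  spec <- nd(outgroup_time, ingroup, "out")
  tbl <- flatten_spec(spec)
  tbl$theta <- theta
  new_species_tree(tbl, n_individuals)
}

#' @rdname species_tree_model
#' @export
radiation_species_tree <- function(theta = 5e-4, n_individuals = 2L,
                                   outgroup_time = 2.25e-4) {
  nd <- node_spec
  labs <- letters[1:18]
  ages <- seq(5e-5, 5.8e-5, length.out = 17)
  cur <- nd(ages[1], labs[17], labs[18])
  for (i in 2:17) cur <- nd(ages[i], labs[18 - i], cur)
  spec <- nd(outgroup_time, cur, "out")
  tbl <- flatten_spec(spec)
  tbl$theta <- theta
  new_species_tree(tbl, n_individuals)
}

#' Hybrid-taxon specification
#'
#' Describes an instantaneous hybrid origin: the hybrid taxon receives equal,
#' unlinked genomic contributions from two parental lineages, each given as
#' the tip labels whose MRCA defines the lineage, diverging from both at time
#' `tau_h`.
#'
#' @param parent_a,parent_b character vectors of tip labels.
#' @param tau_h hybrid origin time (expected substitutions/site).
#' @param label tip label for the hybrid taxon.
#' @export
hybrid_spec <- function(parent_a, parent_b, tau_h, label = "hyb") {
  if (length(intersect(parent_a, parent_b)))
    stop("parental lineages overlap")
  structure(list(parent_a = parent_a, parent_b = parent_b,
                 tau_h = tau_h, label = label),
            class = "hybrid_spec")
}
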