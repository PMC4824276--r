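# Internal helpers: deterministic seed derivation, RNG scoping, bipartition keys.

# Multiplicative string hash folded into [1, 2^31 - 1]. Used to derive
# per-series and per-replicate seeds from the master seed so that results are
# independent of scheduling order. Arithmetic stays below 2^53, so the double
# representation is exact.
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1)
  bytes <- utf8ToInt(paste(c(format(master, scientific = FALSE), ...), collapse = "\r"))
  h <- 104729
  for (b in bytes) h <- (h * 69069 + b) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Canonical key for the bipartition {side, leaves \ side}: the side not
# containing `ref`, sorted and collapsed. Returns NA for trivial bipartitions
# (a side with fewer than 2 leaves).
bipart_key <- function(side, leaves, ref) {
  if (ref %in% side) side <- setdiff(leaves, side)
  if (length(side) < 2L || length(side) > length(leaves) - 2L) return(NA_character_)
  paste(sort(side), collapse = ";")
}

key_leaves <- function(key) strsplit(key, ";", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
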