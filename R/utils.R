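# Internal helpers shared across modules.

#' The six rate-of-change variables
#'
#' Canonical names and order of the six analysed categories: resources (RES),
#' community composition (BCC), single-cell characteristics (SCC),
#' physiological structure (PS), bacterial abundance (BA) and community
#' metabolism (BCM).  Columns of a rate table and nodes of every candidate
#' causal structure use these names; each column holds a rate of change per
#' hour along a transition.
#'
#' @return Character vector of length 6.
#' @export
rate_variables <- function() {
  c("RES", "BCC", "SCC", "PS", "BA", "BCM")
}

# Derive n independent sub-seeds from one integer master seed.  All package
# randomness flows through this splitter so a single --seed reproduces a run.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# Edge label convention used in coefficient maps: "parent->child".
edge_label <- function(parent, child) paste0(parent, "->", child)

`%||%` <- function(a, b) if (is.null(a)) b else a
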