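#' Read a posterior tree ensemble
#'
#' Reads one or more Newick or Nexus files into a `multiPhylo` ensemble,
#' checking that every tree carries the identical tip set and non-negative
#' branch lengths. Tip labels are normalised (spaces to underscores) to
#' match `species_id` conventions of supertrees.
#'
#' @param paths character vector of Newick (`.nwk`/`.tre`/`.txt`) or Nexus
#'   (`.nex`/`.nexus`) files; multi-tree files are expanded.
#' @return an object of class `multiPhylo`.
#' @export
read_tree_ensemble <- function(paths) {
  trees <- list()
  for (p in paths) {
    tr <- if (grepl("\\.nexus$|\\.nex$", p, ignore.case = TRUE))
      ape::read.nexus(p) else ape::read.tree(p)
    if (is.null(tr)) stop("could not parse tree file: ", p, call. = FALSE)
    if (inherits(tr, "phylo")) tr <- list(tr)
    trees <- c(trees, unclass(tr))
  }
  if (!length(trees)) stop("no trees read", call. = FALSE)
  trees <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    tr$tip.label <- normalize_label(tr$tip.label)
    if (anyDuplicated(tr$tip.label))
      stop("duplicate tip labels in tree ", i, call. = FALSE)
    if (is.null(tr$edge.length))
      stop("tree ", i, " has no branch lengths", call. = FALSE)
    if (any(tr$edge.length < 0))
      stop("negative branch length in tree ", i, call. = FALSE)
    tr
  })
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tl <- sort(trees[[i]]$tip.label)
    if (!identical(tl, ref)) {
      d <- c(setdiff(tl, ref), setdiff(ref, tl))
      stop("tree ", i, " tip set differs from tree 1; symmetric difference: ",
           paste(d, collapse = ", "), call. = FALSE)
    }
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Sample trees from an ensemble
#'
#' Draws `B` trees without replacement, seeded, so the same seed always
#' yields the same subset in the same order.
#'
#' @param trees a `multiPhylo` ensemble (or list of `phylo`).
#' @param B number of trees to draw (default 100).
#' @param seed integer seed.
#' @return a `multiPhylo` of length `B`, with attribute `"indices"`.
#' @export
sample_trees <- function(trees, B = 100L, seed = 1L) {
  n <- length(trees)
  if (B > n) stop("B (", B, ") exceeds ensemble size (", n, ")", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, B))
  out <- trees[idx]
  class(out) <- "multiPhylo"
  attr(out, "indices") <- idx
  out
}

#' Brownian phylogenetic covariance matrix
#'
#' The tips-by-tips variance-covariance matrix implied by Brownian motion:
#' entry (i, j) is the root-to-MRCA shared path length, the diagonal the
#' root-to-tip depths.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
build_vcv <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object", call. = FALSE)
  # a single-internal-node tree is indistinguishable from a rooted star
  if (!ape::is.rooted(tree) && tree$Nnode > 1L)
    stop("tree must be rooted", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  ape::vcv.phylo(tree)
}
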