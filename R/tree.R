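#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' shape-mapping functions need: unique tip labels, non-negative branch
#' lengths, a single tree. Missing branch lengths default to 1 with a warning
#' (squared-change parsimony needs lengths; equal lengths is the neutral
#' choice).
#'
#' @param path Newick file containing one rooted tree.
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) abort("file contains more than one tree")
  if (is.null(tree)) abort("could not parse Newick file")
  validate_phylo(tree)
}

#' Write a phylogeny to a Newick file
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_phylo <- function(tree) {
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; defaulting all to 1")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  tree
}
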