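#' Read a rooted phylogenetic tree from a newick file
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the diversity
#' calculations rely on: unique leaf names, non-negative branch lengths, and
#' missing branch lengths replaced by zero with a warning.
#'
#' @param path newick file (single tree).
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf names in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths read as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Write a tree to a newick file
#' @param tree an [ape::phylo] object.
#' @param path destination file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Index a tree for branch-wise diversity computations. Returns, for the
# edges of tree$edge (root edge excluded), the branch lengths and an
# edge x leaf 0/1 matrix marking which leaves descend from each edge's
# child node; leaves ordered as tree$tip.label.
tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  leaf_desc <- desc[tree$edge[, 2L], , drop = FALSE]
  storage.mode(leaf_desc) <- "double"
  colnames(leaf_desc) <- tree$tip.label
  list(edge_length = tree$edge.length,
       leaf_desc = leaf_desc,
       root_edge = if (!is.null(tree$root.edge)) tree$root.edge else 0,
       tip_label = tree$tip.label)
}
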