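#' Read a rooted phylogeny from newick
#'
#' Thin wrapper around [ape::read.tree()] that assigns deterministic
#' preorder names (`N1`, `N2`, ...) to unlabelled internal nodes so that
#' ancestral reconstructions are addressable across runs.
#'
#' @param path Path to a newick file (or a newick string ending in ";").
#' @param taxa Optional character vector of expected taxa; tree tips
#'   absent from it trigger a warning listing them.
#' @return An [ape::phylo] tree with internal node labels.
#' @export
read_newick_tree <- function(path, taxa = NULL) {
  tr <- if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
        else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ",
         tr$tip.label[duplicated(tr$tip.label)][1L])
  if (!is.null(taxa)) {
    extra <- setdiff(tr$tip.label, taxa)
    if (length(extra))
      warning("tree tips absent from companion matrix: ",
              paste(extra, collapse = ", "))
  }
  name_internal_nodes(tr)
}

#' Deterministically name internal nodes
#'
#' Internal nodes without a label receive `N<i>` where `i` is the node's
#' preorder index (root = 1).  Existing labels are kept.
#'
#' @param tree An `ape::phylo` tree.
#' @return The tree with a full `node.label` vector.
#' @export
name_internal_nodes <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n <- length(tree$tip.label)
  pre <- unique(tree$edge[, 1L])           # internal nodes in preorder
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  idx <- pre - n
  need <- !nzchar(lab[idx]) | is.na(lab[idx])
  lab[idx][need] <- paste0("N", seq_along(pre))[need]
  tree$node.label <- lab
  tree
}

#' Drop taxa from a tree
#'
#' Removes the given tips, suppresses resulting degree-2 nodes and sums
#' branch lengths through them (so root-to-tip path lengths of retained
#' tips are preserved).
#'
#' @param tree An `ape::phylo` tree.
#' @param drop Character vector of tip labels to remove.
#' @return The pruned tree.
#' @export
prune_taxa <- function(tree, drop) {
  missing <- setdiff(drop, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(tree$tip.label) - length(drop) < 2L)
    stop("pruning would leave fewer than 2 tips")
  ape::drop.tip(tree, drop)
}

# node labels for every node id (tips then internals); internals fall back
# to N<preorder> naming when the tree carries no labels
node_label_vector <- function(tree) {
  if (is.null(tree$node.label) || !all(nzchar(tree$node.label)))
    tree <- name_internal_nodes(tree)
  c(tree$tip.label, tree$node.label)
}
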