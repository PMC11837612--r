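#' Rooted species phylogeny with labelled internal nodes
#'
#' A `phylogeny` wraps an [ape::read.tree()] `phylo` object together with
#' precomputed parent pointers, node depths and a label index, so that
#' ancestor queries (the workhorse of gain-node mapping) are cheap and the
#' node labelling is stable across runs.  Internal nodes without labels in
#' the source newick are assigned deterministic preorder labels
#' `N1 ... Nk` (the root is always `N1`), so gain maps are reproducible.
#'
#' @param tree an [ape] `phylo` object; must be rooted.
#' @return an object of class `phylogeny`: a list with elements
#'   `tree` (the `phylo`), `n_tip`, `n_node` (tips + internals),
#'   `root` (node number), `parent` (integer vector, 0 at the root),
#'   `children` (list of integer vectors), `depth` (edges from root),
#'   `labels` (character, node number to node ID) and `index`
#'   (named integer, node ID to node number).
#' @export
as_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L)
    stop("leaf names are not unique: ", paste(unique(dup), collapse = ", "))

  n_tip  <- length(tree$tip.label)
  n_all  <- n_tip + tree$Nnode
  root   <- n_tip + 1L
  parent <- integer(n_all)
  children <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; c <- tree$edge[i, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }

  # explicit preorder DFS: depths and deterministic internal labels
  depth <- integer(n_all)
  preorder <- integer(n_all)
  stack <- root; k <- 0L
  while (length(stack) > 0L) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; preorder[k] <- nd
    kids <- children[[nd]]
    if (length(kids) > 0L) {
      depth[kids] <- depth[nd] + 1L
      stack <- c(stack, rev(kids))
    }
  }

  labels <- character(n_all)
  labels[seq_len(n_tip)] <- tree$tip.label
  internal_pre <- preorder[preorder > n_tip]
  have <- tree$node.label
  use_own <- !is.null(have) && length(have) == tree$Nnode &&
    all(nzchar(have)) && !anyDuplicated(have) &&
    !any(have %in% tree$tip.label)
  if (use_own) {
    labels[(n_tip + 1L):n_all] <- have
  } else {
    labels[internal_pre] <- paste0("N", seq_along(internal_pre))
    tree$node.label <- labels[(n_tip + 1L):n_all]
  }

  structure(list(
    tree = tree, n_tip = n_tip, n_node = n_all, root = root,
    parent = parent, children = children, depth = depth,
    labels = labels,
    index = stats::setNames(seq_len(n_all), labels)
  ), class = "phylogeny")
}

#' Read a rooted tree from a newick file
#'
#' @param path path to a single-tree newick file.
#' @param outgroup optional leaf name; if the tree is unrooted it is rooted
#'   on the branch leading to this leaf.  An unrooted tree with no outgroup
#'   is an error.
#' @return a [as_phylogeny()] object.
#' @export
read_newick <- function(path, outgroup = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree in ", path)
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup))
      stop("tree in ", path, " is unrooted and no outgroup was given")
    if (!outgroup %in% tree$tip.label)
      stop("outgroup '", outgroup, "' is not a leaf of the tree")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  as_phylogeny(tree)
}

#' @export
print.phylogeny <- function(x, ...) {
  cat("phylogeny: ", x$n_tip, " leaves, ", x$n_node - x$n_tip,
      " internal nodes, root = ", x$labels[x$root], "\n", sep = "")
  invisible(x)
}

#' Leaf names of a phylogeny
#' @param phy a `phylogeny`.
#' @return character vector of leaf names.
#' @export
leaves <- function(phy) phy$tree$tip.label

node_number <- function(phy, node_id) {
  i <- phy$index[node_id]
  if (anyNA(i)) {
    bad <- node_id[is.na(i)]
    stop("unknown node(s): ", paste(bad, collapse = ", "))
  }
  unname(i)
}

#' Leaf descendants of a node
#' @param phy a `phylogeny`.
#' @param node_id a node ID (leaf name or internal label).
#' @return character vector of leaf names under (and including) the node.
#' @export
descendant_leaves <- function(phy, node_id) {
  nd <- node_number(phy, node_id)
  out <- integer(0); stack <- nd
  while (length(stack) > 0L) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x <= phy$n_tip) out <- c(out, x)
    else stack <- c(stack, phy$children[[x]])
  }
  phy$labels[sort(out)]
}

#' Is `ancestor` an ancestor-or-equal of `node`?
#' @param phy a `phylogeny`.
#' @param ancestor,node node IDs.
#' @return logical scalar.
#' @export
is_ancestor <- function(phy, ancestor, node) {
  a <- node_number(phy, ancestor); x <- node_number(phy, node)
  while (x != 0L) {
    if (x == a) return(TRUE)
    x <- phy$parent[x]
  }
  FALSE
}

#' Internal node IDs
#' @param phy a `phylogeny`.
#' @return character vector of internal node labels (preorder).
#' @export
internal_nodes <- function(phy) phy$labels[(phy$n_tip + 1L):phy$n_node]
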