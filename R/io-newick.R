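#' Read a tree from a newick file or string
#'
#' Trees are handled as `ape` `"phylo"` objects throughout the package.
#' Bootstrap supports, when present, are stored as internal-node labels (the
#' common newick dialect).
#'
#' @param path Path to a newick file, or a newick string ending in `;`.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- if (grepl(";", path, fixed = TRUE) && !file.exists(path)) {
    ape::read.tree(text = path)
  } else {
    if (!file.exists(path)) stop_ctx("newick file not found: %s", path)
    ape::read.tree(path)
  }
  if (is.null(tr)) stop_ctx("could not parse newick input (unbalanced parentheses?)")
  if (anyDuplicated(tr$tip.label)) {
    stop_ctx("duplicate leaf labels in tree: %s",
             paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (!is.null(tr$edge.length) && any(!is.finite(tr$edge.length) | tr$edge.length < 0)) {
    stop_ctx("tree has non-finite or negative branch lengths")
  }
  tr
}

#' Write a tree to a newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @param digits Number of digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

# Canonical bipartitions (splits) of an unrooted tree: for every internal
# edge, the sorted leaf set on the side not containing the alphabetically
# first leaf; returned as collapsed strings for set comparison.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  splits <- character(0)
  internal_children <- tree$edge[, 2][tree$edge[, 2] > ntip]
  for (node in internal_children) {
    tips <- tree$tip.label[tips_under(tree, node)]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next
    side <- if (anchor %in% tips) setdiff(tree$tip.label, tips) else tips
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

# Tip indices below `node` (which may itself be a tip).
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

# Robinson-Foulds distance between two unrooted trees on the same leaves.
rf_distance <- function(t1, t2) {
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
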