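# Outgroup rooting and anchor-based clade grouping of a supplied tree.
# Tree inference itself is consumed as a newick file.

#' Reroot a tree at a named outgroup leaf
#'
#' Places the root on the branch subtending the outgroup leaf. Leaf-set
#' bipartitions of the unrooted topology are preserved.
#'
#' @param tree An `ape::phylo` object or a newick string/file path.
#' @param outgroup_leaf Leaf label (must be present exactly once).
#' @return Rooted `phylo` object.
#' @export
reroot_at_outgroup <- function(tree, outgroup_leaf) {
  tree <- as_phylo(tree)
  n <- sum(tree$tip.label == outgroup_leaf)
  if (n == 0L) {
    if (!is.null(tree$node.label) && outgroup_leaf %in% tree$node.label) {
      stop("outgroup must be a leaf, not an internal node: ", outgroup_leaf)
    }
    stop("outgroup leaf absent from tree: ", outgroup_leaf)
  }
  if (n > 1L) stop("ambiguous outgroup leaf name: ", outgroup_leaf)
  ape::root(tree, outgroup = outgroup_leaf, resolve.root = TRUE)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, a newick string, or a file path")
}

#' Assign leaves to named groups via anchor leaves
#'
#' Each group is the leaf set of the smallest clade (MRCA clade) containing
#' all of its anchors; overlapping group clades are an error, as is an
#' absent anchor. Leaves covered by no group are left unassigned.
#'
#' @param tree Rooted `phylo` object.
#' @param anchors Named list of character vectors: group label -> anchor
#'   leaves (disjoint, non-empty).
#' @return data.frame (leaf, group); attribute `group_sizes` gives clade
#'   sizes.
#' @export
assign_groups <- function(tree, anchors) {
  tree <- as_phylo(tree)
  stopifnot(is.list(anchors), length(anchors) >= 1L, !is.null(names(anchors)))
  if (any(lengths(anchors) == 0L)) stop("empty anchor set")
  all_anchors <- unlist(anchors, use.names = FALSE)
  if (anyDuplicated(all_anchors)) {
    stop("anchor sets are not disjoint: ", paste(unique(all_anchors[duplicated(all_anchors)]), collapse = ", "))
  }
  absent <- setdiff(all_anchors, tree$tip.label)
  if (length(absent) > 0L) stop("anchor leaf absent from tree: ", paste(absent, collapse = ", "))
  clades <- lapply(anchors, function(a) {
    if (length(a) == 1L) return(a)
    node <- ape::getMRCA(tree, a)
    ape::extract.clade(tree, node)$tip.label
  })
  groups <- names(anchors)
  for (i in seq_along(clades)) {
    for (j in seq_along(clades)) {
      if (i < j && length(intersect(clades[[i]], clades[[j]])) > 0L) {
        stop("overlapping group clades: ", groups[i], " and ", groups[j])
      }
    }
  }
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(leaf = clades[[g]], group = g, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "group_sizes") <- stats::setNames(lengths(clades), groups)
  out
}

#' Species composition of each group
#'
#' @param assignment Output of [assign_groups()].
#' @param species_of Named character vector leaf -> species.
#' @return data.frame (group, species, n) with counts summing to the number
#'   of assigned leaves.
#' @export
group_composition <- function(assignment, species_of) {
  missing <- setdiff(assignment$leaf, names(species_of))
  if (length(missing) > 0L) {
    stop("leaf without species mapping: ", paste(missing, collapse = ", "))
  }
  sp <- unname(species_of[assignment$leaf])
  tab <- as.data.frame(table(group = assignment$group, species = sp),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3] <- "n"
  tab <- tab[order(tab$group, -tab$n, tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
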