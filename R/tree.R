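#' Read a rooted, labelled species tree
#'
#' The tree must be rooted and contain the focal (human) leaf. Internal node
#' labels are preserved; they name the human-lineage ancestors used for
#' dating.
#'
#' @param path Path to a newick file.
#' @param human Name of the focal leaf. Default `"human"`.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(path, human = "human") {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  validate_species_tree(tr, human = human)
  tr
}

#' Write a species tree to newick
#'
#' @param tree A `"phylo"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_species_tree <- function(tree, human = "human") {
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!human %in% tree$tip.label)
    stop("species tree has no '", human, "' leaf")
  invisible(tree)
}

#' Ordered human-lineage ancestor path
#'
#' Internal-node labels on the path from the focal leaf's parent up to the
#' root, most recent first. These labels are the ordinal age scale of the
#' whole pipeline.
#'
#' @param tree A rooted `"phylo"` object with internal node labels.
#' @param human Focal leaf name.
#' @return Character vector of ancestor labels, recent to ancient.
#' @export
ancestor_path <- function(tree, human = "human") {
  validate_species_tree(tree, human)
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label)))
    stop("species tree has no internal node labels")
  ntip <- length(tree$tip.label)
  node <- match(human, tree$tip.label)
  root <- ntip + 1L
  path <- integer(0)
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parent) == 0L) break
    path <- c(path, parent)
    node <- parent
  }
  labs <- tree$node.label[path - ntip]
  if (anyDuplicated(labs[nzchar(labs)]))
    stop("ancestor path labels must be unique")
  labs
}

#' Prune a species tree to a subset of leaves
#'
#' Returns the induced subtree: degree-2 internal nodes are collapsed with
#' their branch lengths summed, and surviving node labels are preserved.
#'
#' @param tree Full species tree.
#' @param species_present Leaf names to keep (must include `human`).
#' @param human Focal leaf name.
#' @return Pruned `"phylo"` object.
#' @export
prune_tree <- function(tree, species_present, human = "human") {
  if (!human %in% species_present)
    stop("cannot prune away the '", human, "' leaf")
  missing <- setdiff(species_present, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "))
  if (length(species_present) < 2L)
    stop("cannot prune to fewer than 2 leaves")
  ape::keep.tip(tree, species_present)
}

#' Label of a tree node, or "human" for the focal branch
#' @noRd
node_label <- function(tree, node, human = "human") {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- tree$node.label[node - ntip]
  if (is.null(lab) || !nzchar(lab)) stop("unlabelled internal node ", node)
  lab
}

#' Leaves descending from a named node
#' @noRd
clade_leaves <- function(tree, label, human = "human") {
  ntip <- length(tree$tip.label)
  if (label %in% tree$tip.label) return(label)
  idx <- match(label, tree$node.label)
  if (is.na(idx)) stop("no node labelled '", label, "' in tree")
  node <- ntip + idx
  ape::extract.clade(tree, node)$tip.label
}

#' Ordinal age of a node label on the ancestor path
#'
#' `human` (or any leaf) has age 0; ancestors count up toward the root.
#' @noRd
node_age <- function(label, path, human = "human") {
  if (label == human) return(0L)
  idx <- match(label, path)
  if (is.na(idx)) stop("node '", label, "' is not on the ancestor path")
  idx
}

#' Date a presence pattern by Dollo parsimony
#'
#' Under Dollo parsimony (single gain, any number of losses) the origin of a
#' presence/absence character is the most recent common ancestor of all
#' positive taxa. The focal human leaf is always included.
#'
#' @param tree Rooted labelled species tree.
#' @param present_species Character vector of species with inferred presence.
#' @param human Focal leaf name.
#' @return Ancestor label on the human lineage (or `human` when presence is
#'   human-specific).
#' @export
dollo_age <- function(tree, present_species, human = "human") {
  validate_species_tree(tree, human)
  present <- union(present_species, human)
  bad <- setdiff(present, tree$tip.label)
  if (length(bad))
    stop("species not in tree: ", paste(bad, collapse = ", "))
  if (length(present) == 1L) return(human)
  mrca <- ape::getMRCA(tree, present)
  node_label(tree, mrca, human)
}
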