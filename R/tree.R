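# Newick tree IO with explicit branch-length units.

.tree_units <- c("none", "subst_per_site", "coalescent_units", "Ma")

#' Read a Newick tree
#'
#' A thin wrapper over [ape::read.tree()] that normalizes tip labels
#' (whitespace to underscore), rejects negative branch lengths, and tags the
#' tree with the unit its branch lengths are measured in.
#'
#' @param path File path (or a connection understood by `ape`).
#' @param length_unit One of `"none"`, `"subst_per_site"`,
#'   `"coalescent_units"`, `"Ma"`.
#' @param text Optional Newick string read instead of `path`.
#' @return An [ape::phylo] object with attribute `length_unit`.
#' @export
read_tree <- function(path = NULL, length_unit = .tree_units, text = NULL) {
  length_unit <- match.arg(length_unit)
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  tr$tip.label <- .normalize_taxa(tr$tip.label)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length(s) in tree")
  attr(tr, "length_unit") <- length_unit
  tr
}

#' Write a tree as Newick
#' @param tree A `phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Set the branch-length unit tag of a tree
#' @param tree A `phylo`.
#' @param length_unit See [read_tree()].
#' @return The tree with its `length_unit` attribute set.
#' @export
set_length_unit <- function(tree, length_unit = .tree_units) {
  attr(tree, "length_unit") <- match.arg(length_unit)
  tree
}
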