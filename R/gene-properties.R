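# Per-orthogroup filtering properties: occupancy, tree length, saturation,
# compositional heterogeneity (RCFV) and mean patristic distance, plus
# ranking/subsetting and the variable-site proportion of a supermatrix.

#' Occupancy of a gene alignment
#'
#' Fraction of the full study taxon set present in the alignment.
#'
#' @param alignment An `msa`.
#' @param full_taxon_set Character vector of all study taxa.
#' @return A fraction in \[0, 1\].
#' @export
occupancy <- function(alignment, full_taxon_set) {
  if (!length(full_taxon_set)) stop("empty taxon set")
  full_taxon_set <- .normalize_taxa(full_taxon_set)
  extra <- setdiff(alignment$taxa, full_taxon_set)
  if (length(extra))
    stop("alignment taxa not in full_taxon_set: ", paste(extra, collapse = ", "))
  length(alignment$taxa) / length(full_taxon_set)
}

#' Total gene-tree length
#'
#' Sum of all branch lengths; used as the per-gene substitution-rate proxy.
#'
#' @param gene_tree A `phylo` with branch lengths.
#' @return Non-negative numeric.
#' @export
tree_length <- function(gene_tree) {
  if (is.null(gene_tree$edge.length)) stop("tree has no branch lengths")
  sum(gene_tree$edge.length)
}

#' Mean patristic distance of a gene tree
#'
#' Mean over all unordered leaf pairs of the path-length distance.
#'
#' @param gene_tree A `phylo` with branch lengths and >= 2 leaves.
#' @return Non-negative numeric.
#' @export
mean_patristic <- function(gene_tree) {
  if (is.null(gene_tree$edge.length)) stop("tree has no branch lengths")
  if (ape::Ntip(gene_tree) < 2L) stop("need at least two leaves")
  d <- ape::cophenetic.phylo(gene_tree)
  mean(d[upper.tri(d)])
}

# Pairwise uncorrected p-distances; columns with gap/unknown in either
# sequence are ignored per pair.  Returns a symmetric matrix with NA where
# no comparable column exists.
.p_distances <- function(alignment) {
  m <- as.matrix(alignment)
  excl <- c("-", unknown_symbol(alignment$alphabet))
  n <- nrow(m)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  diag(out) <- 0
  ok <- !(m %in% excl)
  dim(ok) <- dim(m)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- ok[i, ] & ok[j, ]
    if (any(use)) out[i, j] <- out[j, i] <- mean(m[i, use] != m[j, use])
  }
  out
}

#' Saturation of a gene
#'
#' One minus the least-squares through-origin slope of pairwise uncorrected
#' p-distances regressed on pairwise patristic distances, over all taxon
#' pairs shared between the alignment and the gene tree.  Unsaturated genes
#' score near 0; saturated genes approach 1 as p-distances plateau.
#'
#' @param alignment An `msa`.
#' @param gene_tree A `phylo` with branch lengths.
#' @return Numeric <= 1.  The number of skipped (non-shared or
#'   non-comparable) pairs is attached as attribute `n_skipped`.
#' @export
saturation <- function(alignment, gene_tree) {
  shared <- intersect(alignment$taxa, gene_tree$tip.label)
  if (length(shared) < 3L) stop("need >= 3 taxa shared between alignment and tree")
  pd <- .p_distances(alignment)[shared, shared]
  td <- ape::cophenetic.phylo(gene_tree)[shared, shared]
  iu <- upper.tri(pd)
  x <- td[iu]; y <- pd[iu]
  use <- !is.na(y)
  n_skipped <- sum(!use) +
    (choose(length(alignment$taxa), 2) + choose(ape::Ntip(gene_tree), 2) -
       2 * choose(length(shared), 2))
  x <- x[use]; y <- y[use]
  if (all(x == 0)) stop("all patristic distances are zero")
  slope <- sum(x * y) / sum(x * x)
  structure(1 - slope, n_skipped = n_skipped)
}

#' Relative Composition Frequency Variability (RCFV)
#'
#' Taxon-wise compositional heterogeneity:
#' \deqn{RCFV = \sum_{s} \sum_{t} | f_{s,t} - \bar f_s | / n_{taxa}}
#' with per-taxon state frequencies computed over non-gap, non-unknown
#' residues.
#'
#' @param alignment An `msa` with >= 2 taxa.
#' @return Non-negative numeric.
#' @export
rcfv <- function(alignment) {
  if (length(alignment$taxa) < 2L) stop("need >= 2 taxa")
  m <- as.matrix(alignment)
  states <- alphabet_states(alignment$alphabet)
  counts <- t(apply(m, 1L, function(r) tabulate(match(r, states), length(states))))
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("taxon with zero scored residues: ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  freq <- counts / tot
  grand <- colMeans(freq)
  sum(abs(sweep(freq, 2L, grand))) / nrow(m)
}

#' Assemble the per-gene property table
#'
#' @param alignments Named list of `msa` objects.
#' @param gene_trees List of `phylo` objects, parallel to `alignments`.
#' @param full_taxon_set Character vector of all study taxa.
#' @return Data frame with one [gene property record][rank_and_subset] per
#'   gene: `gene`, `occupancy`, `tree_length`, `saturation`, `rcfv`,
#'   `mean_patristic`.
#' @export
gene_property_table <- function(alignments, gene_trees, full_taxon_set) {
  stopifnot(length(alignments) == length(gene_trees))
  gn <- vapply(seq_along(alignments), function(i) {
    nm <- alignments[[i]]$name
    if (is.null(nm)) nm <- names(alignments)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("gene", i)
    nm
  }, character(1))
  data.frame(
    gene = gn,
    occupancy = vapply(alignments, occupancy, numeric(1), full_taxon_set),
    tree_length = vapply(gene_trees, tree_length, numeric(1)),
    saturation = vapply(seq_along(alignments), function(i)
      as.numeric(saturation(alignments[[i]], gene_trees[[i]])), numeric(1)),
    rcfv = vapply(alignments, rcfv, numeric(1)),
    mean_patristic = vapply(gene_trees, mean_patristic, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Rank genes by a property and keep the best K
#'
#' High occupancy is best; low tree length (substitution rate), saturation,
#' RCFV and mean patristic distance are best.  Ties are broken by gene id
#' (lexicographic), so subsets are stable and nested in K.
#'
#' @param records Data frame from [gene_property_table()].
#' @param property One of `"occupancy"`, `"tree_length"`, `"saturation"`,
#'   `"rcfv"`, `"mean_patristic"`.
#' @param k Number of genes to keep (<= number of records).
#' @return Character vector of `k` gene ids, best first.
#' @export
rank_and_subset <- function(records, property, k) {
  props <- c(occupancy = -1, tree_length = 1, saturation = 1, rcfv = 1,
             mean_patristic = 1)
  if (!property %in% names(props))
    stop("unknown property: ", property)
  if (k > nrow(records)) stop("k exceeds the number of records")
  ord <- order(props[[property]] * records[[property]], records$gene)
  records$gene[ord][seq_len(k)]
}

#' Proportion of variable sites
#'
#' Fraction of columns with at least two distinct non-gap, non-unknown
#' states.
#'
#' @param alignment An `msa` (typically a supermatrix).
#' @return A fraction in \[0, 1\].
#' @export
proportion_variable_sites <- function(alignment) {
  m <- as.matrix(alignment)
  if (!length(m)) stop("empty alignment")
  n_distinct <- integer(ncol(m))
  for (s in alphabet_states(alignment$alphabet))
    n_distinct <- n_distinct + (colSums(m == s) > 0L)
  mean(n_distinct >= 2L)
}
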