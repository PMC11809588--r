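# Marginal ancestral-state reconstruction for morphological matrices.

#' Marginal ancestral states of a morphological matrix
#'
#' Maximum-likelihood marginal reconstruction (re-rooted pruning with a
#' uniform root prior) per internal node and character.  A state is
#' *resolved* where its marginal probability exceeds `threshold`, otherwise
#' the cell is reported ambiguous.  Missing and inapplicable cells
#' contribute equal probabilities over all states.
#'
#' @param tree A `phylo` with branch lengths over the matrix taxa.
#' @param mm A [morph_matrix()].
#' @param model An [mk_model()]; its `k` must cover all observed states.
#' @param threshold Resolution threshold on the maximum marginal
#'   probability (default 0.69).
#' @return An `ancestral_states` list: `probabilities` (array
#'   `[node, state, character]`), `resolved` (character matrix node x
#'   character, `NA` where ambiguous), `threshold`.
#' @export
ancestral_states <- function(tree, mm, model, threshold = 0.69) {
  stopifnot(inherits(mm, "morph_matrix"))
  X <- .morph_as_int(mm)
  V <- mk_marginals(tree, X, model)
  nodes <- dimnames(V)[[1]]
  nch <- dim(V)[3]
  res <- matrix(NA_character_, length(nodes), nch,
                dimnames = list(nodes, colnames(mm$mat)))
  for (i in seq_along(nodes)) for (j in seq_len(nch)) {
    p <- V[i, , j]
    if (max(p) > threshold) res[i, j] <- mm$symbols[which.max(p)]
  }
  structure(list(probabilities = V, resolved = res, threshold = threshold),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("<ancestral_states> ", nrow(x$resolved), " nodes x ", ncol(x$resolved),
      " characters; ", sum(!is.na(x$resolved)), " cells resolved at > ",
      x$threshold, "\n", sep = "")
  invisible(x)
}
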