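# Minimum-change (parsimony) step counts for a single character:
# generalized Sankoff dynamic programming with unit costs for unordered
# characters and |i-j| ladder costs for ordered ones.

#' Parsimony steps of one character on a tree
#'
#' Fitch-style minimum change count for unordered characters; dynamic
#' programming over the linear state ladder (costs `|i - j|`) for ordered
#' ones.  Missing and inapplicable tips are unconstrained; tips absent from
#' `states` are treated as missing.
#'
#' @param tree A `phylo` (branch lengths unused).
#' @param states Named vector of states over tips: integers, digit strings,
#'   `"?"`/`"-"`/`NA` for missing.
#' @param ordered Logical flag.
#' @return Integer minimum number of changes.
#' @export
parsimony_steps <- function(tree, states, ordered = FALSE) {
  v <- states
  if (is.character(v)) {
    v[v %in% c("?", "-")] <- NA
    v <- stats::setNames(suppressWarnings(as.integer(v)), names(states))
  }
  v <- v[!is.na(v)]
  scored <- intersect(names(v), tree$tip.label)
  if (length(scored) < 2L) stop("need >= 2 scored tips")
  v <- v[scored]
  su <- sort(unique(v))
  if (length(su) == 1L) return(0L)
  # state universe: the full ladder for ordered, observed set otherwise
  uni <- if (ordered) seq(min(su), max(su)) else su
  k <- length(uni)
  C <- if (ordered) abs(outer(uni, uni, "-")) else 1 - diag(k)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  cost <- vector("list", nn)
  for (i in seq_len(ntip)) {
    tl <- tree$tip.label[i]
    ci <- rep(0, k)
    if (tl %in% names(v)) {
      ci <- rep(Inf, k)
      ci[match(v[[tl]], uni)] <- 0
    }
    cost[[i]] <- ci
  }
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    inc <- apply(C + rep(cost[[ch]], each = k), 1L, min)
    cost[[pa]] <- if (is.null(cost[[pa]])) inc else cost[[pa]] + inc
  }
  as.integer(min(cost[[ntip + 1L]]))
}
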