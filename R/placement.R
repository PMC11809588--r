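# Likelihood-based phylogenetic placement of a query taxon on a reference
# tree from weighted morphological characters.
#
# For every reference edge the query is attached at the edge midpoint with
# a pendant branch whose length is optimized; the edge score is the sum of
# per-character weighted Mk log-likelihoods (gamma rate variation and the
# Lewis variable-characters correction applied on the extended tree).
# Partials here are kept unscaled: morphology-scale trees (tens to a few
# hundred tips, k <= 10) stay far from double underflow.

# Unscaled postorder partials plus per-edge S = P %*% D(child).
.mk_down_raw <- function(tree, X, k, el) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  part <- vector("list", nn)
  for (i in seq_len(ntip)) part[[i]] <- .mk_tip_partial(X[i, ], k)
  S <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    S[[e]] <- .mk_prob(k, el[e]) %*% part[[ch]]
    part[[pa]] <- if (is.null(part[[pa]])) S[[e]] else part[[pa]] * S[[e]]
  }
  list(part = part, S = S)
}

# Midpoint vectors for every edge: A (towards the child subtree) and B
# (towards the rest of the tree, root prior folded in).
.mk_edge_vectors <- function(tree, X, k, el) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  dn <- .mk_down_raw(tree, X, k, el)
  U <- vector("list", nn)
  U[[root]] <- matrix(1 / k, k, ncol(X))
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  A <- B <- vector("list", nrow(tree$edge))
  for (e in rev(seq_len(nrow(tree$edge)))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    Vtop <- U[[pa]]
    for (s2 in setdiff(children_of[[as.character(pa)]], e))
      Vtop <- Vtop * dn$S[[s2]]
    Phalf <- .mk_prob(k, el[e] / 2)
    A[[e]] <- Phalf %*% dn$part[[ch]]
    B[[e]] <- Phalf %*% Vtop
    U[[ch]] <- .mk_prob(k, el[e]) %*% Vtop
  }
  list(A = A, B = B)
}

# Group label of the clade below an edge: unanimous label if there is one,
# else the majority (alphabetical tie-break), NA if no tip is mapped.
.edge_group <- function(tree, edge, groups) {
  ch <- tree$edge[edge, 2]
  tips <- if (ch <= ape::Ntip(tree)) tree$tip.label[ch]
          else ape::extract.clade(tree, ch)$tip.label
  g <- groups[tips]
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_character_)
  tab <- sort(table(g), decreasing = TRUE)
  names(tab)[1]
}

#' Place a query taxon on a reference tree
#'
#' @param reference_tree A `phylo`; trees without branch lengths get unit
#'   lengths with a notice.
#' @param mm Reference [morph_matrix()] (taxa must include the reference
#'   tips that are scored; tips absent from the matrix count as all
#'   missing).
#' @param query Character (symbols, `"?"`, `"-"`) or 0-based integer vector
#'   of states, one per character of `mm`.
#' @param model An [mk_model()]; the default mirrors the placement
#'   protocol: 4 gamma categories and the Lewis correction.
#' @param weights Per-character weights (default all 1); see
#'   [calibrate_weights()].
#' @param groups Optional named vector mapping reference tips to group
#'   (family) labels, used for the assigned-group column.
#' @param pendant_bounds Pendant-length bracket for the per-edge
#'   optimization (default `c(1e-8, 10)`).
#' @param query_name Label used in the result.
#' @return A `placement_result` list: `query`, `edges` (data frame ranked
#'   by score with child node, score, pendant length, group), `best_edge`,
#'   `best_child`, `pendant`, `assigned_group`.
#' @export
place_query <- function(reference_tree, mm, query,
                        model = mk_model(2, gamma_categories = 4, alpha = 1,
                                         ascertainment = "lewis_variable"),
                        weights = NULL, groups = NULL,
                        pendant_bounds = c(1e-8, 10), query_name = "query") {
  stopifnot(inherits(mm, "morph_matrix"))
  tree <- ape::reorder.phylo(reference_tree, "postorder")
  if (query_name %in% tree$tip.label)
    stop("query taxon already in the reference tree")
  if (is.null(tree$edge.length)) {
    message("reference tree has no branch lengths; using unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  k <- model$k
  nch <- ncol(mm$mat)
  if (length(query) != nch) stop("query length != number of characters")
  if (is.character(query)) {
    q <- match(query, mm$symbols) - 1L
  } else q <- as.integer(query)
  if (all(is.na(q))) stop("query has no scored characters")
  if (any(q[!is.na(q)] >= k)) stop("query states outside the model's k")
  if (is.null(weights)) weights <- rep(1, nch)
  stopifnot(length(weights) == nch)

  X <- .match_rows(.morph_as_int(mm), tree)
  lewis <- model$ascertainment == "lewis_variable"
  Xall <- X; qall <- q
  if (lewis) {
    Xconst <- matrix(rep(0:(k - 1L), each = nrow(X)), nrow(X), k)
    rownames(Xconst) <- rownames(X)
    Xall <- cbind(X, Xconst)
    qall <- c(q, 0:(k - 1L))
  }
  qpart <- .mk_tip_partial(matrix(qall, nrow = 1)[1, ], k)
  ncat <- length(model$cat_rates)
  EV <- vector("list", ncat)
  for (ci in seq_len(ncat)) {
    el <- tree$edge.length * model$rate * model$cat_rates[ci]
    EV[[ci]] <- .mk_edge_vectors(tree, Xall, k, el)
  }
  n_edges <- nrow(tree$edge)
  score_edge <- function(e, d) {
    lik <- 0
    for (ci in seq_len(ncat)) {
      Pq <- .mk_prob(k, model$rate * model$cat_rates[ci] * d)
      lik <- lik + colSums(EV[[ci]]$A[[e]] * EV[[ci]]$B[[e]] * (Pq %*% qpart))
    }
    lik <- lik / ncat
    if (lewis) {
      cs <- sum(lik[(nch + 1L):(nch + k)])
      if (cs >= 1) return(-Inf)
      lik <- lik[seq_len(nch)] / (1 - cs)
    }
    lik[lik <= 0] <- .Machine$double.xmin
    sum(weights * log(lik))
  }
  res <- data.frame(edge = seq_len(n_edges),
                    child = tree$edge[, 2],
                    child_label = ifelse(tree$edge[, 2] <= ape::Ntip(tree),
                                         tree$tip.label[tree$edge[, 2]],
                                         paste0("node", tree$edge[, 2])),
                    score = NA_real_, pendant = NA_real_,
                    stringsAsFactors = FALSE)
  for (e in seq_len(n_edges)) {
    opt <- optimize_scalar(function(d) score_edge(e, d),
                           pendant_bounds[1], pendant_bounds[2])
    res$score[e] <- opt$value
    res$pendant[e] <- opt$par
  }
  res$group <- if (is.null(groups)) NA_character_
               else vapply(seq_len(n_edges), function(e)
                 .edge_group(tree, e, groups), character(1))
  res <- res[order(-res$score), ]
  rownames(res) <- NULL
  structure(list(query = query_name, edges = res,
                 best_edge = res$edge[1], best_child = res$child[1],
                 pendant = res$pendant[1],
                 assigned_group = res$group[1], tree = tree),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("placement of '%s': best edge above %s (score %.3f%s)\n",
              x$query, x$edges$child_label[1], x$edges$score[1],
              if (!is.na(x$assigned_group))
                paste0(", group ", x$assigned_group) else ""))
  invisible(x)
}

#' Summarize placement accuracy per group
#'
#' Reproduces the per-family accuracy table of a placement experiment:
#' one row per truth group with species count, correct count and the
#' percentage (two decimals), plus aggregate rows for queries whose truth
#' group is present in the reference tree, absent from it (always zero
#' correct by construction), and overall.
#'
#' @param assigned Named character vector: query -> assigned group.
#' @param truth Named character vector: query -> true group (must cover
#'   every placed query).
#' @param reference_groups Character vector of group labels present in the
#'   reference tree.
#' @return Data frame `group`, `n_species`, `n_correct`, `percentage`,
#'   `in_reference`, `aggregate`.
#' @export
summarize_placements <- function(assigned, truth, reference_groups) {
  if (!all(names(assigned) %in% names(truth)))
    stop("every placement needs a truth group")
  truth <- truth[names(assigned)]
  correct <- !is.na(assigned) & assigned == truth
  row_of <- function(label, idx, in_ref, agg) {
    n <- length(idx); ncor <- sum(correct[idx])
    data.frame(group = label, n_species = n, n_correct = ncor,
               percentage = if (n > 0) round(100 * ncor / n, 2) else NA_real_,
               in_reference = in_ref, aggregate = agg,
               stringsAsFactors = FALSE)
  }
  grps <- sort(unique(truth))
  rows <- lapply(grps, function(g)
    row_of(g, which(truth == g), g %in% reference_groups, FALSE))
  in_ref <- which(truth %in% reference_groups)
  out_ref <- which(!(truth %in% reference_groups))
  rows <- c(rows, list(
    row_of("In the reference tree", in_ref, TRUE, TRUE),
    row_of("Not in the reference tree", out_ref, FALSE, TRUE),
    row_of("Total", seq_along(truth), NA, TRUE)))
  do.call(rbind, rows)
}
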