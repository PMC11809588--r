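# Mk-model likelihood machinery: Felsenstein pruning over batched
# characters, discrete-gamma rate variation, the Lewis (variable-characters)
# ascertainment correction, and inside-outside passes for marginal
# ancestral states and per-edge placement vectors.
#
# Characters are handled as integer matrices (taxa x characters, 0-based
# states, NA = missing/inapplicable); partial likelihoods are k x nchar
# matrices rescaled per node, with per-character log scaling tracked
# separately.

#' Specify an Mk model
#'
#' @param k Number of states (>= 2).
#' @param rate Overall rate multiplier (> 0).
#' @param gamma_categories Number of discrete-gamma rate categories
#'   (1 = no rate variation).
#' @param alpha Gamma shape; required when `gamma_categories > 1`.
#' @param ascertainment `"none"` or `"lewis_variable"` (condition on
#'   characters being variable).
#' @return An `mk_model` list with the category rates precomputed
#'   (equal-probability categories represented by their means, mean 1).
#' @export
mk_model <- function(k, rate = 1, gamma_categories = 1, alpha = NULL,
                     ascertainment = c("none", "lewis_variable")) {
  ascertainment <- match.arg(ascertainment)
  stopifnot(k >= 2, rate > 0, gamma_categories >= 1)
  cat_rates <- if (gamma_categories > 1) {
    if (is.null(alpha)) stop("alpha required for gamma rate variation")
    phangorn::discrete.gamma(alpha, gamma_categories)
  } else 1
  structure(list(k = as.integer(k), rate = rate,
                 gamma_categories = as.integer(gamma_categories),
                 alpha = alpha, cat_rates = cat_rates,
                 ascertainment = ascertainment),
            class = "mk_model")
}

# Symmetric k-state transition matrix for expected substitutions d.
.mk_prob <- function(k, d) {
  e <- exp(-k * d / (k - 1))
  p_diff <- (1 - e) / k
  P <- matrix(p_diff, k, k)
  diag(P) <- p_diff + e
  P
}

# Tip partials: k x nchar indicator matrix (all ones where NA).
.mk_tip_partial <- function(col, k) {
  nc <- length(col)
  P <- matrix(1, k, nc)
  obs <- which(!is.na(col))
  if (length(obs)) {
    P[, obs] <- 0
    P[cbind(col[obs] + 1L, obs)] <- 1
  }
  P
}

.colmax <- function(x) {
  m <- x[1, ]
  if (nrow(x) > 1L) for (i in 2:nrow(x)) m <- pmax(m, x[i, ])
  m
}

# Postorder (down) pass for one rate category.
# X: taxa x nchar integer matrix, rows matched to tree$tip.label.
# edge_lengths: per-edge expected substitutions (already rate-scaled).
# Returns partials, per-node log-scales, and per-edge S = P %*% D(child).
.mk_down <- function(tree, X, k, edge_lengths, keep_edges = FALSE) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  nc <- ncol(X)
  part <- vector("list", nn)
  sc <- vector("list", nn)
  zero <- numeric(nc)
  for (i in seq_len(ntip)) {
    part[[i]] <- .mk_tip_partial(X[i, ], k)
    sc[[i]] <- zero
  }
  S <- if (keep_edges) vector("list", nrow(tree$edge)) else NULL
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    Se <- .mk_prob(k, edge_lengths[e]) %*% part[[ch]]
    if (keep_edges) S[[e]] <- Se
    if (is.null(part[[pa]])) {
      part[[pa]] <- Se
      sc[[pa]] <- sc[[ch]]
    } else {
      part[[pa]] <- part[[pa]] * Se
      sc[[pa]] <- sc[[pa]] + sc[[ch]]
      mx <- .colmax(part[[pa]])
      mx[mx == 0] <- 1
      part[[pa]] <- sweep(part[[pa]], 2L, mx, "/")
      sc[[pa]] <- sc[[pa]] + log(mx)
    }
  }
  list(part = part, sc = sc, S = S)
}

# Per-character log-likelihood for one category (uniform 1/k root prior).
.mk_cat_loglik <- function(tree, X, k, edge_lengths) {
  dn <- .mk_down(tree, X, k, edge_lengths)
  root <- ape::Ntip(tree) + 1L
  log(colSums(dn$part[[root]]) / k) + dn$sc[[root]]
}

# log-mean-exp across categories (rows = categories).
.log_mean_exp <- function(m) {
  mx <- apply(m, 2L, max)
  mx + log(colMeans(exp(sweep(m, 2L, mx))))
}

# Order X rows to the tree tips; unmatched tips become all-missing rows.
.match_rows <- function(X, tree) {
  out <- matrix(NA_integer_, ape::Ntip(tree), ncol(X),
                dimnames = list(tree$tip.label, colnames(X)))
  shared <- intersect(rownames(X), tree$tip.label)
  out[shared, ] <- X[shared, , drop = FALSE]
  out
}

#' Mk log-likelihoods of a character matrix
#'
#' Pruning-algorithm likelihood with uniform root prior `1/k`.  With gamma
#' rate variation the uncorrected likelihood is averaged over categories;
#' the Lewis correction then divides by one minus the (category-averaged)
#' probability of the k constant patterns.  Missing (`NA`) tips contribute
#' all-ones partials.
#'
#' @param tree A `phylo` with non-negative branch lengths.
#' @param X Integer matrix (taxa x characters, 0-based states, `NA`
#'   missing) with taxon rownames, or a single named vector.
#' @param model An [mk_model()].
#' @param edge_scale Optional per-edge length multipliers (rate-shift
#'   machinery); default 1.
#' @return Numeric vector of per-character log-likelihoods.
#' @export
mk_loglik <- function(tree, X, model, edge_scale = 1) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(names(X), NULL))
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  bad <- X[!is.na(X)]
  if (length(bad) && (min(bad) < 0 || max(bad) >= model$k))
    stop("states outside 0..k-1")
  X <- .match_rows(X, tree)
  k <- model$k
  base_len <- tree$edge.length * edge_scale
  nc <- ncol(X)
  Xall <- X
  n_const <- 0L
  if (model$ascertainment == "lewis_variable") {
    Xconst <- matrix(rep(0:(k - 1L), each = nrow(X)), nrow(X), k,
                     dimnames = list(rownames(X), NULL))
    Xall <- cbind(X, Xconst)
    n_const <- k
  }
  ll_cat <- matrix(NA_real_, length(model$cat_rates), ncol(Xall))
  for (ci in seq_along(model$cat_rates)) {
    ll_cat[ci, ] <- .mk_cat_loglik(tree, Xall, k,
                                   base_len * model$rate * model$cat_rates[ci])
  }
  ll <- .log_mean_exp(ll_cat)
  if (n_const) {
    const_sum <- sum(exp(ll[(nc + 1L):(nc + k)]))
    if (const_sum >= 1) stop("constant-pattern likelihoods sum to >= 1")
    ll <- ll[seq_len(nc)] - log(1 - const_sum)
  }
  unname(ll)
}

#' Log-likelihood of a single character
#'
#' @param tree A `phylo` with branch lengths.
#' @param column Named vector of 0-based states (`NA` missing) over tips.
#' @param model An [mk_model()].
#' @return Scalar log-likelihood.
#' @export
mk_character_loglik <- function(tree, column, model) {
  mk_loglik(tree, column, model)[1]
}

#' Marginal ancestral state probabilities
#'
#' Standard inside-outside (re-rooted pruning) marginals with a uniform
#' root prior, per internal node and character; with gamma rate variation
#' the marginals are averaged over categories weighted by each category's
#' posterior probability.  Conditioning on variability cancels from these
#' conditional probabilities, so no ascertainment term appears.
#'
#' @inheritParams mk_loglik
#' @return A 3-d array `[internal node, state, character]` of posterior
#'   state probabilities (dimnames carry ape node ids).
#' @export
mk_marginals <- function(tree, X, model, edge_scale = 1) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(names(X), NULL))
  tree <- ape::reorder.phylo(tree, "postorder")
  X <- .match_rows(X, tree)
  k <- model$k
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  nc <- ncol(X)
  base_len <- tree$edge.length * edge_scale
  ncat <- length(model$cat_rates)
  V <- array(0, c(tree$Nnode, k, nc))
  logL_cat <- matrix(NA_real_, ncat, nc)
  marg_cat <- vector("list", ncat)
  for (ci in seq_len(ncat)) {
    el <- base_len * model$rate * model$cat_rates[ci]
    dn <- .mk_down(tree, X, k, el, keep_edges = TRUE)
    U <- vector("list", nn)
    U[[root]] <- matrix(1 / k, k, nc)
    logL_cat[ci, ] <- log(colSums(dn$part[[root]] * U[[root]])) + dn$sc[[root]]
    # preorder: reverse of the postorder edge sequence
    children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    for (e in rev(seq_len(nrow(tree$edge)))) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sibs <- setdiff(children_of[[as.character(pa)]], e)
      Vtop <- U[[pa]]
      for (s2 in sibs) Vtop <- Vtop * dn$S[[s2]]
      Uc <- .mk_prob(k, el[e]) %*% Vtop
      mx <- .colmax(Uc); mx[mx == 0] <- 1
      U[[ch]] <- sweep(Uc, 2L, mx, "/")
    }
    m <- array(0, c(tree$Nnode, k, nc))
    for (v in (ntip + 1L):nn) {
      raw <- dn$part[[v]] * U[[v]]
      tot <- colSums(raw); tot[tot == 0] <- 1
      m[v - ntip, , ] <- sweep(raw, 2L, tot, "/")
    }
    marg_cat[[ci]] <- m
  }
  # category posteriors per character
  wmax <- apply(logL_cat, 2L, max)
  w <- exp(sweep(logL_cat, 2L, wmax))
  w <- sweep(w, 2L, colSums(w), "/")
  for (ci in seq_len(ncat))
    V <- V + sweep(marg_cat[[ci]], 3L, w[ci, ], "*")
  dimnames(V) <- list(as.character((ntip + 1L):nn), as.character(0:(k - 1L)),
                      colnames(X))
  V
}
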