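# Independent brute-force oracles used to validate the package's numerics.
# These deliberately avoid the package's internal code paths: likelihoods
# and marginals are computed by exhaustive summation over all ancestral
# state assignments, parsimony by exhaustive minimization.

# Symmetric Mk transition matrix (independent of the package's helper).
oracle_pmat <- function(k, d) {
  e <- exp(-k * d / (k - 1))
  m <- matrix((1 - e) / k, k, k)
  diag(m) <- (1 - e) / k + e
  m
}

# Likelihood of one character pattern by exhaustive enumeration over all
# internal-state assignments (uniform 1/k root prior); col is a named
# 0-based vector over tips, NA = missing.
oracle_pattern_lik <- function(tree, col, k, rate = 1) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  P_edge <- lapply(tree$edge.length, function(l) oracle_pmat(k, rate * l))
  assigns <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  tot <- 0
  for (a in seq_len(nrow(assigns))) {
    full <- integer(nn)
    full[(ntip + 1L):nn] <- assigns[a, ]
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (ch <= ntip) {
        s <- col[tree$tip.label[ch]]
        if (!is.na(s)) pr <- pr * P_edge[[e]][full[pa], s + 1L]
      } else {
        pr <- pr * P_edge[[e]][full[pa], full[ch]]
      }
    }
    tot <- tot + pr
  }
  tot
}

# Gamma-averaged, optionally Lewis-corrected log-likelihood by enumeration.
oracle_loglik <- function(tree, col, k, cat_rates = 1, lewis = FALSE) {
  L <- mean(vapply(cat_rates, function(r)
    oracle_pattern_lik(tree, col, k, r), numeric(1)))
  if (lewis) {
    Lc <- sum(vapply(0:(k - 1L), function(s) {
      cc <- stats::setNames(rep(s, ape::Ntip(tree)), tree$tip.label)
      mean(vapply(cat_rates, function(r)
        oracle_pattern_lik(tree, cc, k, r), numeric(1)))
    }, numeric(1)))
    L <- L / (1 - Lc)
  }
  log(L)
}

# Marginal posterior of one internal node by enumeration (single rate).
oracle_marginal <- function(tree, col, k, node) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  P_edge <- lapply(tree$edge.length, function(l) oracle_pmat(k, l))
  assigns <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  joint <- numeric(k)
  for (a in seq_len(nrow(assigns))) {
    full <- integer(nn)
    full[(ntip + 1L):nn] <- assigns[a, ]
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (ch <= ntip) {
        s <- col[tree$tip.label[ch]]
        if (!is.na(s)) pr <- pr * P_edge[[e]][full[pa], s + 1L]
      } else {
        pr <- pr * P_edge[[e]][full[pa], full[ch]]
      }
    }
    st <- full[node]
    joint[st] <- joint[st] + pr
  }
  joint / sum(joint)
}

# Minimum number of changes by exhaustive assignment search.
oracle_parsimony <- function(tree, col, ordered = FALSE) {
  v <- col[!is.na(col)]
  su <- sort(unique(v))
  uni <- if (ordered) seq(min(su), max(su)) else su
  kk <- length(uni)
  if (kk == 1L) return(0L)
  C <- if (ordered) abs(outer(uni, uni, "-")) else 1 - diag(kk)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  assigns <- as.matrix(expand.grid(rep(list(seq_len(kk)), tree$Nnode)))
  best <- Inf
  for (a in seq_len(nrow(assigns))) {
    full <- integer(ntip + tree$Nnode)
    full[(ntip + 1L):(ntip + tree$Nnode)] <- assigns[a, ]
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (ch <= ntip) {
        s <- col[tree$tip.label[ch]]
        if (!is.na(s)) cost <- cost + C[full[pa], match(s, uni)]
      } else {
        cost <- cost + C[full[pa], full[ch]]
      }
    }
    best <- min(best, cost)
  }
  as.integer(best)
}

# Random small tree with positive branch lengths (independent of the
# package's Yule generator).
oracle_random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  tr
}

# Random gene alignment fixture (no simulator involvement): i.i.d. columns.
random_msa <- function(taxa, n_cols, alphabet = "AA", gap_prob = 0.05) {
  states <- alphabet_states(alphabet)
  m <- matrix(sample(states, length(taxa) * n_cols, replace = TRUE),
              nrow = length(taxa), dimnames = list(taxa, NULL))
  if (gap_prob > 0) {
    hit <- matrix(stats::runif(length(m)) < gap_prob, nrow = nrow(m))
    m[hit] <- "-"
  }
  msa_from_matrix(m, alphabet = alphabet)
}

# Leave-one-out placement experiment used by the module and acceptance
# tests; returns per-query logical success (best edge == true edge or an
# adjacent edge).
loo_placement <- function(tree, mm, model, weights = NULL) {
  results <- logical(0)
  for (tx in tree$tip.label) {
    tip_id <- match(tx, tree$tip.label)
    ped <- tree$edge[tree$edge[, 2] == tip_id, 1]
    kids <- tree$edge[tree$edge[, 1] == ped, 2]
    sib <- setdiff(kids, tip_id)
    if (length(sib) != 1L) next
    sib_tips <- if (sib <= ape::Ntip(tree)) tree$tip.label[sib]
                else ape::extract.clade(tree, sib)$tip.label
    red <- ape::drop.tip(tree, tx)
    mmr <- mm
    mmr$mat <- mmr$mat[red$tip.label, , drop = FALSE]
    pl <- place_query(red, mmr, mm$mat[tx, ], model = model,
                      weights = weights, query_name = tx)
    redpo <- ape::reorder.phylo(red, "postorder")
    tipsets <- lapply(seq_len(nrow(redpo$edge)), function(e) {
      ch <- redpo$edge[e, 2]
      if (ch <= ape::Ntip(redpo)) redpo$tip.label[ch]
      else ape::extract.clade(redpo, ch)$tip.label
    })
    true_e <- which(vapply(tipsets, function(s) setequal(s, sib_tips),
                           logical(1)))
    if (!length(true_e)) next
    adj <- which(apply(redpo$edge, 1L, function(r)
      any(r %in% redpo$edge[true_e, ])))
    results <- c(results, pl$best_edge %in% union(true_e, adj))
  }
  results
}

# The 20-taxon, 100-character Mk recovery fixture shared by the module and
# acceptance placement tests.
placement_fixture <- function(seed = 11, n_taxa = 20, n_chars = 100) {
  tr <- simulate_species_tree(n_taxa, seed = seed)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  sim <- simulate_morph_matrix(tr, n_chars, states_per_char = 2,
                               base_rate = 0.5, rate_gamma_shape = 1.5,
                               seed = seed + 1)
  list(tree = tr, mm = sim$matrix)
}
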