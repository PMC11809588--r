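# Character simulators: i.i.d. sites under a symmetric (Jukes-Cantor-type)
# k-state model on a gene tree, and discrete morphological characters under
# the Mk model with per-character rate multipliers.

# Evolve integer states (1..k) along one branch, vectorized over sites.
# d = expected substitutions; an "event" redraws uniformly among k states,
# so events occur at rate k/(k-1) to give one expected *change* per unit d.
.evolve_states <- function(parent_states, d, k) {
  n <- length(parent_states)
  out <- parent_states
  hit <- stats::runif(n) >= exp(-k / (k - 1) * d)
  nh <- sum(hit)
  if (nh) out[hit] <- sample.int(k, nh, replace = TRUE)
  out
}

# Same but with per-site expected substitutions d (vector), used for
# per-character rate multipliers.
.evolve_states_vec <- function(parent_states, d, k) {
  out <- parent_states
  hit <- stats::runif(length(parent_states)) >= exp(-k / (k - 1) * d)
  nh <- sum(hit)
  if (nh) out[hit] <- sample.int(k, nh, replace = TRUE)
  out
}

# Root-to-tip simulation over an arbitrary phylo; returns integer state
# matrix (rows = all nodes in ape numbering) of 1..k.
.simulate_states_on_tree <- function(tree, n_sites, rate, k,
                                     site_rates = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- ape::Ntip(tree) + tree$Nnode
  root <- ape::Ntip(tree) + 1L
  states <- matrix(NA_integer_, nnode, n_sites)
  states[root, ] <- sample.int(k, n_sites, replace = TRUE)
  for (e in rev(seq_len(nrow(tree$edge)))) {   # preorder
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    d <- rate * tree$edge.length[e]
    if (!is.null(site_rates)) {
      states[ch, ] <- .evolve_states_vec(states[p, ], d * site_rates, k)
    } else {
      states[ch, ] <- .evolve_states(states[p, ], d, k)
    }
  }
  states
}

#' Simulate an alignment on a gene tree
#'
#' Sites are i.i.d.; substitution follows the symmetric k-state
#' (Jukes-Cantor-type) model with `mu * branch length` expected
#' substitutions per site per branch.  With `mu = 0` every row equals the
#' root sequence.
#'
#' @param gene_tree A `phylo` with finite branch lengths.
#' @param n_sites Number of columns.
#' @param mu Mutation rate per site per unit branch length (>= 0).
#' @param alphabet `"DNA"` (4 states) or `"AA"` (20-state Poisson model).
#' @param seed Optional integer seed.
#' @param name Optional alignment name.
#' @return An `msa`.
#' @export
simulate_alignment <- function(gene_tree, n_sites, mu, alphabet = c("DNA", "AA"),
                               seed = NULL, name = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gene_tree$edge.length) || any(!is.finite(gene_tree$edge.length)))
    stop("gene tree needs finite branch lengths")
  if (mu < 0) stop("mu must be non-negative")
  letters_ <- alphabet_states(alphabet)
  k <- length(letters_)
  st <- .simulate_states_on_tree(gene_tree, n_sites, mu, k)
  tips <- st[seq_len(ape::Ntip(gene_tree)), , drop = FALSE]
  m <- matrix(letters_[tips], nrow = nrow(tips))
  rownames(m) <- gene_tree$tip.label
  msa_from_matrix(m, alphabet = alphabet, name = name)
}

#' Simulate a morphological matrix under the Mk model
#'
#' Each character evolves under the symmetric Mk model with
#' `states_per_char` states and a per-character rate multiplier; true node
#' states are recorded so that ancestral-state recovery can be scored.
#'
#' @param tree A `phylo` with branch lengths.
#' @param n_chars Number of characters.
#' @param states_per_char Number of Mk states per character (2--10).
#' @param base_rate Expected state changes per unit branch length for a
#'   rate-1 character.
#' @param rates Optional numeric vector of per-character rate multipliers.
#' @param rate_gamma_shape If given (and `rates` is `NULL`), multipliers are
#'   drawn from a mean-1 gamma distribution with this shape.
#' @param seed Optional integer seed.
#' @return List with `matrix` (a [morph_matrix()]), `node_states` (integer
#'   matrix, all tree nodes x characters, 0-based states) and `rates`.
#' @export
simulate_morph_matrix <- function(tree, n_chars, states_per_char = 2,
                                  base_rate = 1, rates = NULL,
                                  rate_gamma_shape = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(states_per_char)
  if (k < 2L || k > 10L) stop("states_per_char must be in 2..10")
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (is.null(rates)) {
    rates <- if (is.null(rate_gamma_shape)) rep(1, n_chars)
             else stats::rgamma(n_chars, shape = rate_gamma_shape,
                                rate = rate_gamma_shape)
  }
  stopifnot(length(rates) == n_chars)
  st <- .simulate_states_on_tree(tree, n_chars, base_rate, k, site_rates = rates)
  tips <- st[seq_len(ape::Ntip(tree)), , drop = FALSE]
  m <- matrix(as.character(tips - 1L), nrow = nrow(tips))
  rownames(m) <- tree$tip.label
  colnames(m) <- paste0("c", seq_len(n_chars))
  list(matrix = morph_matrix(m, symbols = as.character(0:9)),
       node_states = st - 1L, rates = rates)
}

#' Inject per-taxon missingness
#'
#' Thins a gene set (or blanks morphological cells) until each taxon's
#' presence count matches a target profile, emulating the highly skewed
#' occupancy of transcriptome-derived datasets.
#'
#' @param x A list of `msa` gene alignments, or a [morph_matrix()].
#' @param occupancy_profile Named integer vector: for alignments, the number
#'   of genes each taxon should remain in; for a morphological matrix, the
#'   number of scored (non-missing) cells to keep per taxon.
#' @param seed Optional integer seed.
#' @return Object of the same type as `x`.
#' @export
inject_missingness <- function(x, occupancy_profile, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prof <- occupancy_profile
  if (is.null(names(prof))) stop("occupancy_profile must be named by taxon")
  names(prof) <- .normalize_taxa(names(prof))
  if (inherits(x, "morph_matrix")) {
    for (tx in names(prof)) {
      scored <- which(x$mat[tx, ] != "?")
      tgt <- prof[[tx]]
      if (tgt > length(scored))
        stop("unreachable target for ", tx, ": ", tgt, " > ", length(scored))
      drop <- scored[sample.int(length(scored), length(scored) - tgt)]
      x$mat[tx, drop] <- "?"
    }
    return(x)
  }
  stopifnot(all(vapply(x, inherits, logical(1), "msa")))
  has <- lapply(x, `[[`, "taxa")
  for (tx in names(prof)) {
    in_genes <- which(vapply(has, function(h) tx %in% h, logical(1)))
    tgt <- prof[[tx]]
    if (tgt > length(in_genes))
      stop("unreachable target for ", tx, ": present in ", length(in_genes),
           " gene(s), target ", tgt)
    drop <- in_genes[sample.int(length(in_genes), length(in_genes) - tgt)]
    for (g in drop) {
      a <- x[[g]]
      keep <- setdiff(a$taxa, tx)
      x[[g]] <- msa(a$seqs[keep], alphabet = a$alphabet, name = a$name)
      has[[g]] <- keep
    }
  }
  x
}
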