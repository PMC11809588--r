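# Fast end-to-end simulation of concatenated multilocus matrices for the
# D-statistic machinery: coalescent genealogies are kept in a light internal
# form and sites are simulated directly on them, skipping per-gene phylo
# construction.

# Simulate sites on an internal genealogy from .msc_gene(); returns an
# integer tip-state matrix (taxa x sites, states 1..k).
.gen_sites <- function(gen, n_sites, mu, k) {
  L <- gen$ntip
  nn <- 2L * L - 1L
  states <- matrix(NA_integer_, nn, n_sites)
  states[nn, ] <- sample.int(k, n_sites, replace = TRUE)
  for (i in (nn - 1L):1L) {   # parents always have a larger index
    d <- mu * (gen$time[gen$parent[i]] - gen$time[i])
    states[i, ] <- .evolve_states(states[gen$parent[i], ], d, k)
  }
  out <- states[seq_len(L), , drop = FALSE]
  rownames(out) <- gen$labels
  out
}

#' Simulate a concatenated multilocus coalescent matrix
#'
#' Draws `n_loci` gene genealogies under the multispecies coalescent on
#' `species_tree` (with optional [introgression pulses][introgression_pulse])
#' and simulates `sites_per_locus` i.i.d. symmetric-model sites on each,
#' concatenating everything into one alignment.  This is the generator used
#' for D-statistic calibration and power studies.
#'
#' @param species_tree Ultrametric rooted `phylo` in coalescent units.
#' @param n_loci Number of loci.
#' @param sites_per_locus Columns per locus.
#' @param mu Mutations per site per coalescent unit.
#' @param pulses Optional list of [introgression_pulse()] objects.
#' @param alphabet `"DNA"` or `"AA"`.
#' @param seed Optional integer seed.
#' @return An `msa` of `n_loci * sites_per_locus` columns.
#' @export
simulate_coalescent_supermatrix <- function(species_tree, n_loci,
                                            sites_per_locus, mu,
                                            pulses = NULL,
                                            alphabet = c("DNA", "AA"),
                                            seed = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.null(seed)) set.seed(seed)
  prep <- .msc_prepare(species_tree, pulses)
  letters_ <- alphabet_states(alphabet)
  k <- length(letters_)
  L <- prep$ntip
  big <- matrix(NA_integer_, L, n_loci * sites_per_locus)
  for (g in seq_len(n_loci)) {
    gen <- .msc_gene(prep)
    cols <- ((g - 1L) * sites_per_locus + 1L):(g * sites_per_locus)
    big[, cols] <- .gen_sites(gen, sites_per_locus, mu, k)
  }
  m <- matrix(letters_[big], nrow = L)
  rownames(m) <- prep$tips
  msa_from_matrix(m, alphabet = alphabet, name = "coalescent_loci")
}

#' Quartet species tree for D-statistic studies
#'
#' Builds the caterpillar `(((P1,P2),P3),O)` with split times `t12`, `t123`
#' and `t_root` coalescent units before present.
#'
#' @param t12,t123,t_root Increasing split times.
#' @param labels Tip labels, default `P1, P2, P3, O`.
#' @return An ultrametric `phylo` in coalescent units.
#' @export
quartet_species_tree <- function(t12 = 1, t123 = 2, t_root = 3,
                                 labels = c("P1", "P2", "P3", "O")) {
  stopifnot(t12 < t123, t123 < t_root)
  txt <- sprintf("(((%s:%g,%s:%g):%g,%s:%g):%g,%s:%g);",
                 labels[1], t12, labels[2], t12, t123 - t12,
                 labels[3], t123, t_root - t123, labels[4], t_root)
  read_tree(text = txt, length_unit = "coalescent_units")
}

#' Symmetric five-taxon species tree for D-FOIL studies
#'
#' Builds `((P1,P2),(P3,P4),O)` with the (P1,P2) split at `t12`, the
#' (P3,P4) split at `t34 >= t12`, the pair-ancestor split at `t_pairs` and
#' the root at `t_root`.
#'
#' @param t12,t34,t_pairs,t_root Split times in coalescent units.
#' @param labels Tip labels, default `P1..P4, O`.
#' @return An ultrametric `phylo` in coalescent units.
#' @export
quintet_species_tree <- function(t12 = 1, t34 = 1.5, t_pairs = 2.5, t_root = 4,
                                 labels = c("P1", "P2", "P3", "P4", "O")) {
  stopifnot(t12 <= t34, t34 < t_pairs, t_pairs < t_root)
  txt <- sprintf("(((%s:%g,%s:%g):%g,(%s:%g,%s:%g):%g):%g,%s:%g);",
                 labels[1], t12, labels[2], t12, t_pairs - t12,
                 labels[3], t34, labels[4], t34, t_pairs - t34,
                 t_root - t_pairs, labels[5], t_root)
  read_tree(text = txt, length_unit = "coalescent_units")
}

#' Gene-tree discordance fraction for a rooted triplet
#'
#' Simulates `n_genes` coalescent gene trees on the triplet species tree
#' `((A,B),C)` whose internal branch has length `t` and returns the
#' fraction whose topology does not group A with B.  The multispecies
#' coalescent expects a fraction \eqn{(2/3) e^{-t}}.
#'
#' @param t Internal branch length in coalescent units.
#' @param n_genes Number of gene trees.
#' @param seed Optional integer seed.
#' @param pendant Pendant branch length for A and B (default 1).
#' @return Observed discordance fraction.
#' @export
triplet_discordance <- function(t, n_genes, seed = NULL, pendant = 1) {
  if (!is.null(seed)) set.seed(seed)
  txt <- sprintf("((A:%g,B:%g):%g,C:%g);", pendant, pendant, t, pendant + t)
  sp <- read_tree(text = txt, length_unit = "coalescent_units")
  prep <- .msc_prepare(sp)
  disc <- 0L
  ia <- match("A", prep$tips); ib <- match("B", prep$tips)
  for (g in seq_len(n_genes)) {
    gen <- .msc_gene(prep)
    # first coalescence is node 4 (3 tips); concordant iff it joins A and B
    if (!(gen$parent[ia] == 4L && gen$parent[ib] == 4L)) disc <- disc + 1L
  }
  disc / n_genes
}
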