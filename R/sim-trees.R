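# Tree simulators: Yule species trees (coalescent units) and
# multispecies-coalescent gene trees with optional introgression pulses.
# One haploid lineage is sampled per species.

#' Simulate a Yule species tree
#'
#' Forward-time pure-birth simulation: starting from two lineages, each
#' lineage splits at rate `birth_rate`; the process stops after the
#' (`n_taxa`-1)-th split plus one further exponential waiting time, so that
#' pendant branches are never zero.  The expected root height is
#' \eqn{(1/\lambda)\sum_{k=2}^{n} 1/k}.  Branch lengths are tagged as
#' coalescent units.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param seed Optional integer seed.
#' @param birth_rate Speciation rate per lineage per coalescent unit.
#' @return A rooted binary ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_species_tree <- function(n_taxa, seed = NULL, birth_rate = 1) {
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_taxa)
  slot_parent <- c(n + 1L, n + 1L)
  slot_birth <- c(0, 0)
  next_internal <- n + 2L
  ep <- integer(0); ec <- integer(0); el <- numeric(0)
  t <- 0; k <- 2L
  while (k < n) {
    t <- t + stats::rexp(1, birth_rate * k)
    i <- sample.int(k, 1L)
    nd <- next_internal; next_internal <- next_internal + 1L
    ep <- c(ep, slot_parent[i]); ec <- c(ec, nd); el <- c(el, t - slot_birth[i])
    slot_parent <- c(slot_parent[-i], nd, nd)
    slot_birth <- c(slot_birth[-i], t, t)
    k <- k + 1L
  }
  t_end <- t + stats::rexp(1, birth_rate * n)
  ep <- c(ep, slot_parent); ec <- c(ec, seq_len(n))
  el <- c(el, t_end - slot_birth)
  tr <- structure(list(edge = cbind(ep, ec, deparse.level = 0),
                       edge.length = el,
                       tip.label = paste0("t", seq_len(n)),
                       Nnode = n - 1L), class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "length_unit") <- "coalescent_units"
  tr
}

#' Describe an introgression pulse
#'
#' A single instantaneous gene-flow event: at `time` (coalescent units
#' before the present), a lineage tracing through the recipient population
#' is reassigned to the donor population with probability `gamma` (viewed
#' backward in time).
#'
#' @param donor,recipient Tip label, or character vector of tips whose
#'   covering species-tree branch at `time` defines the population.
#' @param time Pulse time in coalescent units before present.
#' @param gamma Introgression proportion in \[0, 1\].
#' @return An `introgression_pulse` object.
#' @export
introgression_pulse <- function(donor, recipient, time, gamma) {
  stopifnot(time >= 0, gamma >= 0, gamma <= 1)
  structure(list(donor = donor, recipient = recipient,
                 time = time, gamma = gamma), class = "introgression_pulse")
}

# Node times (before present) of an ultrametric tree; errors otherwise.
.node_times <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(ape::Ntip(tree))])
  tt <- h - depth
  if (any(abs(tt[seq_len(ape::Ntip(tree))]) > tol * max(h, 1)))
    stop("species tree must be ultrametric (tips contemporaneous)")
  tt[seq_len(ape::Ntip(tree))] <- 0
  tt
}

# Population (species-tree node id) containing `tips` at time `at`.
.population_at <- function(tree, tt, tips, at) {
  parent <- integer(max(tree$edge)); parent[tree$edge[, 2]] <- tree$edge[, 1]
  v <- if (length(tips) == 1L) match(tips, tree$tip.label)
       else ape::getMRCA(tree, tips)
  if (is.na(v) || is.null(v)) stop("unknown tips: ", paste(tips, collapse = ", "))
  root <- ape::Ntip(tree) + 1L
  while (v != root && tt[parent[v]] <= at) v <- parent[v]
  if (v == root) stop("pulse time ", at, " is at or above the species-tree root")
  v
}

# Precompute everything the per-gene coalescent needs.
.msc_prepare <- function(species_tree, pulses = NULL) {
  if (is.null(species_tree$edge.length)) stop("species tree needs branch lengths")
  tt <- .node_times(species_tree)
  ntip <- ape::Ntip(species_tree)
  parent <- integer(max(species_tree$edge))
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  internal <- ntip + seq_len(species_tree$Nnode)
  children <- lapply(internal, function(v) species_tree$edge[species_tree$edge[, 1] == v, 2])
  names(children) <- internal
  ev <- data.frame(time = tt[internal], type = "merge", node = internal,
                   idx = NA_integer_, stringsAsFactors = FALSE)
  pls <- list()
  if (!is.null(pulses)) {
    if (inherits(pulses, "introgression_pulse")) pulses <- list(pulses)
    for (i in seq_along(pulses)) {
      p <- pulses[[i]]
      mrca_t <- tt[ape::getMRCA(species_tree,
                                unique(c(p$donor, p$recipient)))]
      if (p$time >= mrca_t)
        stop("pulse time must predate the donor-recipient common ancestor")
      pls[[i]] <- list(donor = .population_at(species_tree, tt, p$donor, p$time),
                       recipient = .population_at(species_tree, tt, p$recipient, p$time),
                       gamma = p$gamma)
      ev <- rbind(ev, data.frame(time = p$time, type = "pulse", node = NA_integer_,
                                 idx = i, stringsAsFactors = FALSE))
    }
  }
  # pulses fire before a merge at the same instant
  ev <- ev[order(ev$time, ev$type != "pulse"), ]
  list(ntip = ntip, tt = tt, children = children, events = ev, pulses = pls,
       tips = species_tree$tip.label)
}

# Simulate one gene genealogy; returns parent/time vectors over 2L-1 nodes
# (tips 1..L in species-tree tip order, internals in coalescence order).
.msc_gene <- function(prep) {
  L <- prep$ntip
  lin_pop <- seq_len(L)       # population of each active lineage
  lin_node <- seq_len(L)      # gene-tree node carried by the lineage
  g_parent <- rep(NA_integer_, 2L * L - 1L)
  g_time <- numeric(2L * L - 1L)
  nxt <- L + 1L
  cur <- 0
  seg_times <- c(prep$events$time, Inf)
  for (r in seq_along(seg_times)) {
    te <- seg_times[r]
    # competing coalescent processes across populations until te
    while (length(lin_pop) > 1L) {
      pops <- unique(lin_pop)
      kk <- tabulate(match(lin_pop, pops), length(pops))
      rates <- kk * (kk - 1) / 2
      total <- sum(rates)
      if (total == 0) break
      cand <- cur + stats::rexp(1, total)
      if (cand > te) break
      cur <- cand
      p <- pops[sample.int(length(pops), 1L, prob = rates)]
      idx <- which(lin_pop == p)
      pair <- idx[sample.int(length(idx), 2L)]
      g_parent[lin_node[pair]] <- nxt
      g_time[nxt] <- cur
      lin_node[pair[1]] <- nxt
      lin_pop <- lin_pop[-pair[2]]
      lin_node <- lin_node[-pair[2]]
      nxt <- nxt + 1L
    }
    if (length(lin_pop) <= 1L) break
    cur <- te
    if (r <= nrow(prep$events)) {
      if (prep$events$type[r] == "merge") {
        v <- prep$events$node[r]
        kids <- prep$children[[as.character(v)]]
        lin_pop[lin_pop %in% kids] <- v
      } else {
        pl <- prep$pulses[[prep$events$idx[r]]]
        hit <- lin_pop == pl$recipient & stats::runif(length(lin_pop)) < pl$gamma
        lin_pop[hit] <- pl$donor
      }
    }
  }
  list(parent = g_parent, time = g_time, labels = prep$tips, ntip = L)
}

# Internal genealogy -> ape phylo (coalescent units).
.gen_to_phylo <- function(gen) {
  L <- gen$ntip
  nn <- 2L * L - 1L
  child <- which(!is.na(gen$parent))
  map <- seq_len(nn)
  map[(L + 1L):nn] <- 3L * L - ((L + 1L):nn)   # reverse internals: root -> L+1
  edge <- cbind(map[gen$parent[child]], map[child], deparse.level = 0)
  len <- gen$time[gen$parent[child]] - gen$time[child]
  tr <- structure(list(edge = edge, edge.length = len,
                       tip.label = gen$labels, Nnode = L - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "length_unit") <- "coalescent_units"
  tr
}

#' Simulate multispecies-coalescent gene trees
#'
#' One haploid lineage per species; branch lengths of `species_tree` are in
#' coalescent units.  Within each population, lineage pairs coalesce at rate
#' 1 per pair; populations merge at species-tree nodes.  Each
#' [introgression_pulse()] moves, backward in time, lineages from the
#' recipient to the donor population with probability `gamma` at the pulse
#' time.
#'
#' @param species_tree Ultrametric rooted `phylo` in coalescent units.
#' @param n_genes Number of gene trees.
#' @param pulses Optional list of [introgression_pulse()] objects.
#' @param seed Optional integer seed.
#' @return List of `phylo` gene trees (coalescent units).
#' @export
simulate_msc_gene_trees <- function(species_tree, n_genes, pulses = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prep <- .msc_prepare(species_tree, pulses)
  lapply(seq_len(n_genes), function(i) .gen_to_phylo(.msc_gene(prep)))
}
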