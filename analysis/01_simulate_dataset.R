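#!/usr/bin/env Rscript
# Build the synthetic study dataset every later step consumes: a 40-taxon
# species tree, MSC gene trees and alignments for 300 orthogroups with the
# highly skewed taxon occupancy typical of transcriptome assemblies, and a
# 44-character Mk morphological matrix.  Everything is written under
# results/simdata/.

suppressMessages({library(phylodiag); library(ape)})
set.seed(2026)
outdir <- "results/simdata"
dir.create(file.path(outdir, "genes"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(outdir, "gene_trees"), recursive = TRUE, showWarnings = FALSE)

n_taxa <- 40
n_genes <- 300          # a desk-scale stand-in for the study's ~2,764
sites_per_gene <- 150
mu <- 0.05              # substitutions per site per coalescent unit

species_tree <- simulate_species_tree(n_taxa, seed = 11)
write_tree(species_tree, file.path(outdir, "species_tree.nwk"))

gene_trees <- simulate_msc_gene_trees(species_tree, n_genes, seed = 12)
set.seed(13)
genes <- vector("list", n_genes)
for (i in seq_len(n_genes)) {
  genes[[i]] <- simulate_alignment(gene_trees[[i]], sites_per_gene, mu,
                                   alphabet = "AA",
                                   name = sprintf("og%04d", i))
}

# Skewed occupancy: a core of nearly complete taxa, a tail of sparse ones,
# with the three sparsest present in fewer than 20 genes.
set.seed(14)
quality <- sort(rbeta(n_taxa, 4, 1.2), decreasing = TRUE)
targets <- pmax(5L, round(quality * n_genes))
targets[(n_taxa - 2):n_taxa] <- c(19L, 12L, 8L)
names(targets) <- species_tree$tip.label
genes <- inject_missingness(genes, targets, seed = 15)
# genes need >= 4 taxa to be analysable downstream
genes <- Filter(function(g) length(g$taxa) >= 4, genes)
for (g in genes)
  write_alignment(g, file.path(outdir, "genes", paste0(g$name, ".fasta")))
# gene trees are written in expected substitutions per site (the unit an
# inferred gene tree would carry), i.e. coalescent lengths times mu
for (i in seq_along(gene_trees)) {
  gt <- gene_trees[[i]]
  gt$edge.length <- gt$edge.length * mu
  write_tree(gt, file.path(outdir, "gene_trees", sprintf("og%04d.nwk", i)))
}

# Morphology: 44 characters on a time-like rescaling of the species tree,
# with per-character gamma rate multipliers and realistic missingness.
morph_tree <- species_tree
morph_tree$edge.length <- morph_tree$edge.length /
  max(node.depth.edgelength(morph_tree))
msim <- simulate_morph_matrix(morph_tree, 44, states_per_char = 2,
                              base_rate = 0.5, rate_gamma_shape = 1.5,
                              seed = 16)
mm <- msim$matrix
set.seed(17)
scored_targets <- stats::setNames(
  pmax(10L, rbinom(n_taxa, 44, 0.85)), rownames(mm$mat))
mm <- inject_missingness(mm, scored_targets, seed = 18)
write_morph_nexus(mm, file.path(outdir, "morphology.nex"))
dir.create("scratch", showWarnings = FALSE)
saveRDS(list(node_states = msim$node_states, rates = msim$rates),
        "scratch/morph_truth.rds")   # truth tables: scratch only

# Family map: two disjoint mid-sized clades become famA and famB, the rest
# famC, so the combination scan has three non-trivial groups
internal <- Ntip(species_tree) + seq_len(species_tree$Nnode)
clades <- lapply(internal, function(v) extract.clade(species_tree, v)$tip.label)
sizes <- lengths(clades)
iA <- which(sizes >= 6 & sizes <= 14)[1]
famA_tips <- clades[[iA]]
iB <- which(sizes >= 5 & sizes <= 14 &
            !vapply(clades, function(cl) any(cl %in% famA_tips), logical(1)))[1]
famB_tips <- clades[[iB]]
fams <- rep("famC", n_taxa)
fams[species_tree$tip.label %in% famA_tips] <- "famA"
fams[species_tree$tip.label %in% famB_tips] <- "famB"
writeLines(paste(species_tree$tip.label, fams, sep = "\t"),
           file.path(outdir, "families.tsv"))

occ <- vapply(genes, occupancy, numeric(1), species_tree$tip.label)
cat(sprintf("wrote %d genes (occupancy %.2f-%.2f, median %.2f), %d taxa\n",
            length(genes), min(occ), max(occ), median(occ), n_taxa))
cat(sprintf("sparsest taxa present in %s genes\n",
            paste(sort(head(sort(targets), 3)), collapse = ", ")))
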