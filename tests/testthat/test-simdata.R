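test_that("Yule species trees are reproducible and match the closed-form height", {
  tr <- simulate_species_tree(3, seed = 1)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)
  expect_error(simulate_species_tree(2), "at least 3")

  t1 <- simulate_species_tree(15, seed = 99)
  t2 <- simulate_species_tree(15, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-6))

  # E[root height] = sum_{k=2..n} 1/k for birth rate 1
  set.seed(5)
  n <- 10
  hts <- replicate(1000, max(ape::node.depth.edgelength(simulate_species_tree(n))))
  expect_lt(abs(mean(hts) / sum(1 / (2:n)) - 1), 0.10)
})

test_that("MSC gene-tree discordance matches the coalescent closed form", {
  for (t in c(0.5, 1, 2)) {
    expected <- (2 / 3) * exp(-t)
    n <- 10000
    obs <- triplet_discordance(t, n, seed = round(100 * t))
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(obs - expected), 3 * se)
  }
  # deep split: discordance vanishes
  expect_lt(triplet_discordance(20, 2000, seed = 4), 0.005)
})

test_that("a full-strength pulse re-routes the recipient lineage", {
  # gamma = 1 pulse from C into B above a ((A,B),C) split: B groups with C
  sp <- read_tree(text = "((A:1,B:1):1,C:2);", length_unit = "coalescent_units")
  pulse <- introgression_pulse(donor = "C", recipient = "B", time = 0.5,
                               gamma = 1)
  gts <- simulate_msc_gene_trees(sp, 300, pulses = list(pulse), seed = 8)
  groups_bc <- vapply(gts, function(g) {
    !ape::is.monophyletic(g, c("A", "B"))
  }, logical(1))
  expect_gt(mean(groups_bc), 0.5)

  expect_error(
    simulate_msc_gene_trees(sp, 2, pulses = list(
      introgression_pulse("C", "B", time = 5, gamma = 0.5))),
    "root|ancestor")
})

test_that("sequence simulation obeys the Jukes-Cantor closed form", {
  gt <- read_tree(text = "(A:0.25,B:0.25);", length_unit = "coalescent_units")
  # mu = 0: all rows identical
  a0 <- simulate_alignment(gt, 50, mu = 0, alphabet = "DNA", seed = 2)
  expect_equal(a0$seqs[["A"]], a0$seqs[["B"]])

  n <- 10000
  al <- simulate_alignment(gt, n, mu = 1, alphabet = "DNA", seed = 5)
  m <- as.matrix(al)
  p <- mean(m[1, ] != m[2, ])
  d <- 0.5  # total path length
  expected <- 0.75 * (1 - exp(-4 * d / 3))
  expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / n))

  a1 <- simulate_alignment(gt, 100, mu = 0.3, alphabet = "AA", seed = 9)
  a2 <- simulate_alignment(gt, 100, mu = 0.3, alphabet = "AA", seed = 9)
  expect_identical(a1$seqs, a2$seqs)
})

test_that("Mk character simulation matches the two-state closed form", {
  tr <- read_tree(text = "(A:0.4,B:0.4);")
  sim0 <- simulate_morph_matrix(tr, 30, base_rate = 0, seed = 3)
  expect_true(all(sim0$matrix$mat["A", ] == sim0$matrix$mat["B", ]))

  n <- 10000
  sim <- simulate_morph_matrix(tr, n, states_per_char = 2, base_rate = 1,
                               seed = 4)
  pdiff <- mean(sim$matrix$mat["A", ] != sim$matrix$mat["B", ])
  v <- 0.4
  expected <- (1 - exp(-4 * v)) / 2   # two pendant branches of length v
  expect_lt(abs(pdiff - expected), 3 * sqrt(expected * (1 - expected) / n))

  s1 <- simulate_morph_matrix(tr, 20, seed = 12)
  s2 <- simulate_morph_matrix(tr, 20, seed = 12)
  expect_identical(s1$matrix$mat, s2$matrix$mat)
  # true node states recorded for every node
  expect_equal(nrow(s1$node_states), ape::Ntip(tr) + tr$Nnode)
})

test_that("missingness injection hits the occupancy profile exactly", {
  set.seed(21)
  taxa <- paste0("t", 1:6)
  genes <- lapply(1:40, function(i) {
    a <- random_msa(taxa, 20, "AA", gap_prob = 0)
    a$name <- paste0("g", i)
    a
  })
  profile <- stats::setNames(c(40L, 40L, 5L, 17L, 30L, 2L), taxa)
  thinned <- inject_missingness(genes, profile, seed = 6)
  counts <- vapply(taxa, function(tx)
    sum(vapply(thinned, function(a) tx %in% a$taxa, logical(1))), integer(1))
  expect_equal(unname(counts), unname(profile))
  # occupancy recomputed by the gene-properties module agrees
  occ <- vapply(thinned, occupancy, numeric(1), taxa)
  expect_equal(sum(occ) * length(taxa), sum(profile))

  expect_error(inject_missingness(genes, stats::setNames(41L, "t1")),
               "unreachable")
  # full-presence targets leave the set unchanged
  same <- inject_missingness(genes, stats::setNames(rep(40L, 6), taxa))
  expect_identical(lapply(same, `[[`, "seqs"), lapply(genes, `[[`, "seqs"))
})
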