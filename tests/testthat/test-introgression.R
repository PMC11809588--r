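make_quartet_msa <- function(cols) {
  # cols: character vector of 4-residue strings (P1, P2, P3, O per column)
  m <- do.call(cbind, strsplit(cols, ""))
  rownames(m) <- c("P1", "P2", "P3", "O")
  msa_from_matrix(m, alphabet = "DNA")
}

test_that("quartet site patterns are counted per definition", {
  spec <- quartet_spec("P1", "P2", "P3", "O")
  cols <- c(rep("ACCA", 3),   # ABBA: P2,P3 share derived C
            "CACA",           # BABA
            rep("AAAA", 6))
  a <- make_quartet_msa(cols)
  pc <- count_quartet_patterns(a, spec)
  expect_equal(pc$n_abba, 3L)
  expect_equal(pc$n_baba, 1L)
  expect_gte(pc$n_informative, 4L)
  expect_equal(pc$n_sites_scanned, 10L)

  # a gap anywhere removes the site from all counts
  gap <- make_quartet_msa(c("ACC-", "ACCA"))
  pc2 <- count_quartet_patterns(gap, spec)
  expect_equal(pc2$n_abba, 1L)
  expect_equal(pc2$n_informative, 1L)

  # three states at a site is not biallelic
  tri <- make_quartet_msa("ACGA")
  expect_equal(count_quartet_patterns(tri, spec)$n_informative, 0L)

  expect_error(count_quartet_patterns(a, quartet_spec("P1", "P2", "ZZ", "O")),
               "absent")
})

test_that("pattern counts match a brute-force per-column classifier", {
  set.seed(8)
  spec <- quartet_spec("P1", "P2", "P3", "O")
  for (i in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "-"), 4 * 500, replace = TRUE,
                       prob = c(0.4, 0.4, 0.08, 0.02, 0.1)), nrow = 4,
                dimnames = list(c("P1", "P2", "P3", "O"), NULL))
    a <- msa_from_matrix(m, "DNA")
    pc <- count_quartet_patterns(a, spec)
    brute <- apply(m, 2, function(col) {
      if (any(col %in% c("-", "N"))) return("skip")
      if (length(unique(col)) != 2) return("other")
      anc <- col[4]
      d <- col != anc
      if (!d[1] && d[2] && d[3]) return("ABBA")
      if (d[1] && !d[2] && d[3]) return("BABA")
      "informative"
    })
    expect_equal(pc$n_abba, sum(brute == "ABBA"))
    expect_equal(pc$n_baba, sum(brute == "BABA"))
    expect_equal(pc$n_informative, sum(brute %in% c("ABBA", "BABA", "informative")))
  }
})

test_that("Patterson's D follows its formula and exact symmetry", {
  spec <- quartet_spec("P1", "P2", "P3", "O")
  cols <- c(rep("ACCA", 300), rep("CACA", 100), rep("AAAA", 1800))
  a <- make_quartet_msa(sample(cols))
  r <- patterson_d(a, spec, block_size = 200)
  expect_equal(r$D, (300 - 100) / 400)
  expect_identical(r$significant, abs(r$z) >= 3)

  # equal counts: D = 0
  eq <- make_quartet_msa(c(rep("ACCA", 50), rep("CACA", 50), rep("AAAA", 500)))
  expect_equal(patterson_d(eq, spec, block_size = 100)$D, 0)

  # swapping P1 and P2 negates D exactly
  sp <- quartet_species_tree()
  aln <- simulate_coalescent_supermatrix(sp, 300, 200, 0.01, seed = 3)
  d12 <- patterson_d(aln, quartet_spec("P1", "P2", "P3", "O"))
  d21 <- patterson_d(aln, quartet_spec("P2", "P1", "P3", "O"))
  expect_equal(d12$D, -d21$D, tolerance = 1e-12)
  expect_equal(d12$se, d21$se, tolerance = 1e-12)

  expect_error(patterson_d(make_quartet_msa(rep("AAAA", 3000)), spec),
               "informative")
  expect_error(patterson_d(make_quartet_msa(rep("ACCA", 500)), spec,
                           block_size = 1000), "two jackknife blocks")
})

test_that("the jackknife SE is invariant to block-order permutation", {
  set.seed(10)
  sp <- quartet_species_tree()
  aln <- simulate_coalescent_supermatrix(sp, 200, 200, 0.02, seed = 4)
  spec <- quartet_spec("P1", "P2", "P3", "O")
  bs <- 1000
  r1 <- patterson_d(aln, spec, block_size = bs)
  m <- as.matrix(aln)
  nb <- ncol(m) %/% bs
  perm <- sample(nb)
  cols <- unlist(lapply(perm, function(b) ((b - 1) * bs + 1):(b * bs)))
  a2 <- msa_from_matrix(m[, cols], "DNA")
  r2 <- patterson_d(a2, spec, block_size = bs)
  expect_equal(r1$D, r2$D, tolerance = 1e-12)
  expect_equal(r1$se, r2$se, tolerance = 1e-12)
})

test_that("family-combination matrices honor the presence filter", {
  set.seed(44)
  taxa <- c("a1", "a2", "b1", "b2", "c1", "c2", "OG")
  genes <- lapply(1:12, function(i) {
    keep <- sample(taxa, sample(4:7, 1))
    a <- random_msa(keep, 30, "AA", gap_prob = 0)
    a$name <- paste0("g", i)
    a
  })
  groups <- list(c("a1", "a2"), c("b1", "b2"), c("c1", "c2"))
  cm <- enumerate_combination_matrices(genes, groups, "OG")
  expect_length(cm, 8L)
  for (entry in cm) {
    four <- unlist(entry$spec[c("p1", "p2", "p3", "outgroup")])
    expected_genes <- Filter(function(a) all(four %in% a$taxa), genes)
    expect_equal(entry$n_genes, length(expected_genes))
    if (is.null(entry$alignment)) next
    expect_setequal(entry$alignment$taxa, four)
    expect_equal(msa_length(entry$alignment),
                 sum(vapply(expected_genes, msa_length, integer(1))))
  }
  # group sizes multiplying to 75 give 75 matrices
  g75 <- list(paste0("x", 1:5), paste0("y", 1:5), paste0("z", 1:3))
  one_gene <- list(random_msa(c(unlist(g75), "OG"), 10, "AA", gap_prob = 0))
  expect_length(enumerate_combination_matrices(one_gene, g75, "OG"), 75L)
  expect_error(enumerate_combination_matrices(genes, list("a1", character(0),
                                                          "c1"), "OG"), "empty")
})

test_that("D-FOIL statistics are zero on symmetric counts and classify pulses", {
  spec <- dfoil_spec("P1", "P2", "P3", "P4", "O")
  # perfectly symmetric sharing counts: every statistic 0, class none
  sym_cols <- c(rep("CACAA", 10), rep("ACCAA", 10), rep("CAACA", 10),
                rep("ACACA", 10), rep("AAAAA", 200))
  m <- do.call(cbind, strsplit(sym_cols, ""))
  rownames(m) <- c("P1", "P2", "P3", "P4", "O")
  r <- dfoil(msa_from_matrix(m, "DNA"), spec, min_informative = 10)
  expect_equal(unname(r$stats), rep(0, 4))
  expect_equal(r$class, "none")

  # insufficient data guard
  small <- dfoil(msa_from_matrix(m[, 1:30], "DNA"), spec)
  expect_equal(small$class, "insufficient data")

  # relabelling symmetries on one simulated dataset
  sp <- quintet_species_tree()
  aln <- simulate_coalescent_supermatrix(
    sp, 500, 200, 0.01,
    pulses = list(introgression_pulse("P3", "P1", 0.5, 0.5)), seed = 19)
  r0 <- dfoil(aln, spec)
  r12 <- dfoil(aln, dfoil_spec("P2", "P1", "P3", "P4", "O"))
  expect_equal(unname(r12$stats["DFO"]), unname(r0$stats["DIL"]), tolerance = 1e-12)
  expect_equal(unname(r12$stats["DIL"]), unname(r0$stats["DFO"]), tolerance = 1e-12)
  expect_equal(unname(r12$stats["DFI"]), -unname(r0$stats["DFI"]), tolerance = 1e-12)
  expect_equal(unname(r12$stats["DOL"]), unname(r0$stats["DOL"]), tolerance = 1e-12)
  r34 <- dfoil(aln, dfoil_spec("P1", "P2", "P4", "P3", "O"))
  expect_equal(unname(r34$stats["DFO"]), -unname(r0$stats["DIL"]), tolerance = 1e-12)
  expect_equal(unname(r34$stats["DOL"]), -unname(r0$stats["DOL"]), tolerance = 1e-12)
  expect_equal(unname(r34$stats["DFI"]), unname(r0$stats["DFI"]), tolerance = 1e-12)
})

test_that("a strong P1-P3 pulse is classified as P1<->P3 in most replicates", {
  sp <- quintet_species_tree()
  spec <- dfoil_spec("P1", "P2", "P3", "P4", "O")
  hits <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    aln <- simulate_coalescent_supermatrix(
      sp, 400, 200, 0.01,
      pulses = list(introgression_pulse("P1", "P3", 0.5, 0.5)),
      seed = 500 + i)
    r <- dfoil(aln, spec)
    if (r$class == "P1<->P3") hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})
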