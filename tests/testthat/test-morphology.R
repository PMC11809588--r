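test_that("MORD distances match hand computation and stay in [0,1]", {
  m <- rbind(A = c("0", "1", "0", "2"),
             B = c("1", "1", "?", "0"),
             C = c("0", "0", "1", "1"))
  mm <- morph_matrix(m, ordered = c(FALSE, FALSE, FALSE, TRUE))
  D <- mord_distances(mm)
  # A-B over chars 1,2,4: 1, 0, |2-0|/2 -> mean 2/3
  expect_equal(D["A", "B"], 2 / 3, tolerance = 1e-12)
  # A-C over all four: 0, 1, 1, |2-1|/2 -> mean 0.625
  expect_equal(D["A", "C"], 0.625, tolerance = 1e-12)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))

  ident <- morph_matrix(rbind(A = c("0", "1"), B = c("0", "1")))
  expect_equal(mord_distances(ident)["A", "B"], 0)
  opp <- morph_matrix(rbind(A = c("0", "0"), B = c("1", "1")))
  expect_equal(mord_distances(opp)["A", "B"], 1)
  # no comparable character: flagged undefined
  nc <- morph_matrix(rbind(A = c("0", "?"), B = c("?", "1")))
  expect_true(is.na(mord_distances(nc)["A", "B"]))
  expect_error(mord_distances(morph_matrix(rbind(A = c("0", "1")))), "2 taxa")
})

test_that("implied weights follow f = k/(k + es)", {
  quartet <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- rbind(A = c("0", "0", "0"),
             B = c("0", "1", "?"),
             C = c("1", "0", "?"),
             D = c("1", "1", "?"))
  mm <- morph_matrix(m)
  iw <- implied_weights(mm, quartet, concavity = 3)
  # char 1: clean split, steps 1, es 0 -> f = 1
  expect_equal(iw$fit[1], 1)
  # char 2: B and D share 1 across the split, steps 2, es 1 -> 3/4
  expect_equal(iw$fit[2], 0.75)
  # char 3: single scored taxon -> undefined
  expect_false(iw$defined[3])

  # steps agree with the exhaustive oracle on random fixtures
  set.seed(64)
  for (i in 1:10) {
    tr <- oracle_random_tree(5)
    col <- stats::setNames(sample(c(0:2, NA), 5, replace = TRUE), tr$tip.label)
    if (sum(!is.na(col)) < 2) next
    mmr <- morph_matrix(matrix(ifelse(is.na(col), "?", as.character(col)),
                               ncol = 1, dimnames = list(names(col), "c1")))
    expect_equal(implied_weights(mmr, tr)$steps[1],
                 oracle_parsimony(tr, col))
  }
})

test_that("calibrated weights have mean one and penalize fast characters", {
  set.seed(15)
  tr <- simulate_species_tree(15, seed = 51)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  slow <- simulate_morph_matrix(tr, 40, base_rate = 0.3, seed = 52)$matrix
  fast <- simulate_morph_matrix(tr, 40, base_rate = 3, seed = 53)$matrix
  both <- morph_matrix(cbind(slow$mat, fast$mat))
  w <- calibrate_weights(both, tr, concavity = 3)
  expect_equal(mean(w[attr(w, "fits")$defined]), 1, tolerance = 1e-12)
  expect_gt(mean(w[1:40]), mean(w[41:80]))

  # homoplasy-free matrix: all weights exactly 1
  clean <- simulate_morph_matrix(tr, 10, base_rate = 1e-9, seed = 54)$matrix
  w0 <- calibrate_weights(clean, tr)
  expect_true(all(abs(w0 - 1) < 1e-12))
})

test_that("k-means partitioning picks separable clusters and matches brute force", {
  p0 <- partition_characters_kmeans(rep(0.5, 6), seed = 1)
  expect_equal(p0$k, 1L)
  expect_equal(unname(p0$wss[1]), 0)

  p2 <- partition_characters_kmeans(c(0, 0, 0, 10, 10, 10), seed = 1)
  expect_equal(p2$k, 2L)
  expect_length(unique(p2$clusters[1:3]), 1L)
  expect_length(unique(p2$clusters[4:6]), 1L)
  expect_false(p2$clusters[1] == p2$clusters[4])

  # chosen clustering's SS equals an exhaustive 1-D split search (optimal
  # 1-D clusters are contiguous in sorted order)
  set.seed(30)
  x <- round(runif(8), 3)
  for (k in 2:3) {
    pk <- partition_characters_kmeans(x, seed = 2, k_override = k)
    xs <- sort(x)
    splits <- utils::combn(7, k - 1)
    best <- Inf
    for (j in seq_len(ncol(splits))) {
      bounds <- c(0, splits[, j], 8)
      ss <- sum(vapply(seq_len(k), function(b) {
        seg <- xs[(bounds[b] + 1):bounds[b + 1]]
        sum((seg - mean(seg))^2)
      }, numeric(1)))
      best <- min(best, ss)
    }
    expect_equal(unname(pk$wss[as.character(k)]), best, tolerance = 1e-9)
  }
})

test_that("ancestral states resolve obvious nodes and stay calibrated", {
  tr <- read_tree(text = "((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3);")
  mm <- morph_matrix(rbind(A = "0", B = "0", C = "0", D = "0"))
  anc <- ancestral_states(tr, mm, mk_model(2))
  expect_true(all(anc$resolved == "0"))
  expect_true(all(abs(apply(anc$probabilities, c(1, 3), sum) - 1) < 1e-9))

  # balanced quartet, tips 0,0,1,1: the root is exactly ambiguous
  mm2 <- morph_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  anc2 <- ancestral_states(tr, mm2, mk_model(2), threshold = 0.69)
  root_p <- anc2$probabilities["5", , 1]
  expect_equal(unname(root_p), c(0.5, 0.5), tolerance = 1e-10)
  expect_true(is.na(anc2$resolved["5", 1]))
})

test_that("rate-shift AIC weights behave and recover simulated shifts", {
  w <- aic_weights(c(-100, -101), c(1, 1))
  expect_equal(round(w$weight, 4), c(0.7311, 0.2689))
  expect_equal(sum(w$weight), 1)

  set.seed(3)
  tr <- simulate_species_tree(12, seed = 21)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  cladeA <- ape::extract.clade(tr, ape::Ntip(tr) + 2L)$tip.label
  schemes <- list(single = list(edge_blocks = NULL, char_blocks = NULL),
                  shifted = list(edge_blocks = list(cladeA), char_blocks = NULL))

  # single-rate data: the single-rate scheme wins
  sim1 <- simulate_morph_matrix(tr, 200, base_rate = 1, seed = 22)
  rt1 <- test_rates(tr, sim1$matrix, schemes)
  expect_gt(rt1$weight[rt1$scheme == "single"], 0.5)

  # 5x contrast in cladeA: the partitioned scheme wins decisively
  trpo <- ape::reorder.phylo(tr, "postorder")
  eb <- edge_blocks_from_clades(trpo, list(cladeA))
  tr5 <- trpo
  tr5$edge.length <- trpo$edge.length * ifelse(eb == 2L, 5, 1)
  sim5 <- simulate_morph_matrix(tr5, 200, base_rate = 1, seed = 23)
  rt5 <- test_rates(trpo, sim5$matrix, schemes)
  expect_gt(rt5$weight[rt5$scheme == "shifted"], 0.9)

  empty <- morph_matrix(rbind(A = "?", B = "?", C = "0", D = "1"))
  expect_error(test_rates(tr, empty,
                          list(s = list(edge_blocks = NULL,
                                        char_blocks = NULL))),
               NA)  # missing-heavy matrices are legal as long as data exist
})

test_that("character-partition rate schemes are identifiable and fittable", {
  set.seed(4)
  tr <- simulate_species_tree(10, seed = 31)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  slow <- simulate_morph_matrix(tr, 100, base_rate = 0.4, seed = 32)$matrix
  fast <- simulate_morph_matrix(tr, 100, base_rate = 2.5, seed = 33)$matrix
  mm <- morph_matrix(cbind(slow$mat, fast$mat))
  cb <- rep(1:2, each = 100)
  rt <- test_rates(tr, mm, list(
    one_rate = list(edge_blocks = NULL, char_blocks = NULL),
    two_classes = list(edge_blocks = NULL, char_blocks = cb)))
  expect_gt(rt$weight[rt$scheme == "two_classes"], 0.9)
  fits <- attr(rt, "fits")
  expect_equal(fits$two_classes$n_par, 2L)
})

test_that("per-taxon distance comparison averages both tables", {
  md <- matrix(c(0, 0.2, 0.4, 0.2, 0, 0.6, 0.4, 0.6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  mo <- md * 2
  cmp <- morpho_molecular_comparison(md, mo)
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$mean_morph[cmp$taxon == "A"], mean(c(0.2, 0.4)))
  expect_equal(cmp$mean_mol, cmp$mean_morph * 2)
  expect_error(morpho_molecular_comparison(md,
    matrix(0, 1, 1, dimnames = list("Z", "Z"))), "share no taxa")

  ident <- morph_matrix(rbind(X = c("0", "1"), Y = c("0", "1")))
  dd <- mord_distances(ident)
  cmp2 <- morpho_molecular_comparison(dd, dd)
  expect_equal(cmp2$mean_morph, c(0, 0))
})
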