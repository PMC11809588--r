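test_that("pruning likelihood reproduces simple closed forms", {
  # two leaves, same state, pendant length v each, 2 states, no correction:
  # L = sum_root pi * P(root->tip)^2 -> 1/2 as v -> 0
  v <- 1e-8
  tr <- read_tree(text = sprintf("(A:%g,B:%g);", v, v))
  col <- c(A = 0L, B = 0L)
  expect_equal(exp(mk_character_loglik(tr, col, mk_model(2))), 0.5,
               tolerance = 1e-6)

  # zero-length star tree, all tips equal: uncorrected L = 1/k
  for (k in 2:4) {
    star <- read_tree(text = "(A:0,B:0,C:0);")
    col <- c(A = 1L, B = 1L, C = 1L)
    expect_equal(exp(mk_character_loglik(star, col, mk_model(k))), 1 / k,
                 tolerance = 1e-12)
  }
})

test_that("likelihoods, marginals and parsimony match exhaustive enumeration", {
  set.seed(2024)
  n_fix <- 40
  for (i in seq_len(n_fix)) {
    n <- sample(3:5, 1)
    k <- sample(2:4, 1)
    tr <- oracle_random_tree(n)
    col <- stats::setNames(sample(c(0:(k - 1L), NA), n, replace = TRUE),
                           tr$tip.label)
    if (all(is.na(col))) col[1] <- 0L
    gamma <- runif(1) < 0.5
    mod <- if (gamma) mk_model(k, gamma_categories = 4, alpha = 0.8)
           else mk_model(k)
    lewis <- runif(1) < 0.5
    if (lewis)
      mod <- mk_model(k, gamma_categories = mod$gamma_categories,
                      alpha = mod$alpha, ascertainment = "lewis_variable")
    expect_equal(mk_loglik(tr, col, mod)[1],
                 oracle_loglik(tr, col, k, mod$cat_rates, lewis),
                 tolerance = 1e-10)

    V <- mk_marginals(tr, col, mk_model(k))
    for (v in (n + 1L):(n + tr$Nnode)) {
      expect_equal(unname(V[as.character(v), , 1]),
                   oracle_marginal(tr, col, k, v), tolerance = 1e-10)
    }

    scored <- col[!is.na(col)]
    if (length(scored) >= 2) {
      ord <- runif(1) < 0.5
      expect_identical(parsimony_steps(tr, col, ordered = ord),
                       oracle_parsimony(tr, col, ordered = ord))
    }
  }
})

test_that("likelihood is invariant under state relabelling", {
  set.seed(5)
  tr <- oracle_random_tree(6)
  k <- 3
  col <- stats::setNames(sample(0:(k - 1L), 6, replace = TRUE), tr$tip.label)
  perm <- sample(0:(k - 1L))
  col2 <- stats::setNames(perm[col + 1L], names(col))
  mod <- mk_model(k, gamma_categories = 4, alpha = 1,
                  ascertainment = "lewis_variable")
  expect_equal(mk_loglik(tr, col, mod), mk_loglik(tr, col2, mod),
               tolerance = 1e-12)
})

test_that("Lewis-corrected variable-pattern likelihoods sum to one", {
  tr <- read_tree(text = "((A:0.3,B:0.7):0.4,C:1.1);")
  k <- 2
  mod <- mk_model(k, ascertainment = "lewis_variable")
  pats <- expand.grid(rep(list(0:(k - 1L)), 3))
  variable <- pats[apply(pats, 1, function(r) length(unique(r)) > 1), ]
  tot <- sum(apply(variable, 1, function(r) {
    col <- stats::setNames(as.integer(r), c("A", "B", "C"))
    exp(mk_character_loglik(tr, col, mod))
  }))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("parsimony handles the textbook cases", {
  quartet <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(parsimony_steps(quartet, c(A = 0, B = 0, C = 0, D = 0)), 0L)
  expect_equal(parsimony_steps(quartet, c(A = 0, B = 0, C = 1, D = 1)), 1L)
  # ordered ladder: 0 and 2 cost two steps even without an observed 1
  expect_equal(parsimony_steps(quartet, c(A = 0, B = 0, C = 2, D = 2),
                               ordered = TRUE), 2L)
  expect_equal(parsimony_steps(quartet, c(A = "0", B = "?", C = "-", D = "0")), 0L)
  expect_error(parsimony_steps(quartet, c(A = "?", B = "?", C = "?", D = "?")),
               "scored")
})

test_that("scalar optimization refines maxima and honors boundaries", {
  quad <- function(x) -(x - 2)^2
  opt <- optimize_scalar(quad, 0, 10)
  expect_equal(opt$par, 2, tolerance = 1e-5)
  mono <- optimize_scalar(function(x) -x, 0.5, 10)
  expect_equal(mono$par, 0.5, tolerance = 1e-6)
  expect_error(optimize_scalar(function(x) NaN, 0, 1), "non-finite")
})

test_that("optimization recovers the simulated Mk rate", {
  set.seed(31)
  tr <- simulate_species_tree(10, seed = 61)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  true_rate <- 0.8
  sim <- simulate_morph_matrix(tr, 500, states_per_char = 2,
                               base_rate = true_rate, seed = 62)
  X <- matrix(match(sim$matrix$mat, sim$matrix$symbols) - 1L,
              nrow = nrow(sim$matrix$mat),
              dimnames = dimnames(sim$matrix$mat))
  obj <- function(r) sum(mk_loglik(tr, X, mk_model(2, rate = r)))
  opt <- optimize_scalar(obj, 0.05, 10)
  # curvature-based SE from a finite-difference Hessian
  h <- 1e-3
  d2 <- (obj(opt$par + h) - 2 * obj(opt$par) + obj(opt$par - h)) / h^2
  se <- sqrt(-1 / d2)
  expect_lt(abs(opt$par - true_rate), 2 * se)
})
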