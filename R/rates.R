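# Rate-shift model selection on a chronogram: each candidate scheme
# partitions branches and/or characters into blocks with one free rate
# multiplier per block; schemes are compared by AIC weights.

# Fit one scheme.  edge_blocks: integer/factor over edges (NULL = single
# block); char_blocks: ditto over characters.  Branch length used for
# character j on edge e is time_e * r[edge block] * s[char block]; the
# first character-block rate is fixed to 1 whenever both partitions are
# free, for identifiability.
.fit_rate_scheme <- function(tree, X, model, edge_blocks, char_blocks) {
  ne <- nrow(tree$edge)
  nc <- ncol(X)
  if (is.null(edge_blocks)) edge_blocks <- rep(1L, ne)
  if (is.null(char_blocks)) char_blocks <- rep(1L, nc)
  edge_blocks <- as.integer(as.factor(edge_blocks))
  char_blocks <- as.integer(as.factor(char_blocks))
  stopifnot(length(edge_blocks) == ne, length(char_blocks) == nc)
  n_eb <- max(edge_blocks); n_cb <- max(char_blocks)
  for (b in seq_len(n_cb))
    if (all(is.na(X[, char_blocks == b]))) stop("character block ", b, " has no data")
  fix_first_char <- n_eb >= 1 && n_cb > 1
  n_par <- n_eb + if (fix_first_char) n_cb - 1L else 0L
  # with a single character block all rate freedom lives in the edge rates
  if (n_cb == 1L) n_par <- n_eb
  loglik_for <- function(logpar) {
    r_edge <- exp(logpar[seq_len(n_eb)])
    s_char <- if (n_cb > 1L) c(1, exp(logpar[n_eb + seq_len(n_cb - 1L)])) else 1
    ll <- 0
    for (b in seq_len(n_cb)) {
      cols <- which(char_blocks == b)
      ll <- ll + sum(mk_loglik(tree, X[, cols, drop = FALSE], model,
                               edge_scale = r_edge[edge_blocks] * s_char[b]))
    }
    ll
  }
  if (n_par == 1L) {
    opt <- optimize_scalar(function(lr) loglik_for(lr), log(1e-4), log(1e4),
                           tol = 1e-8)
    list(loglik = opt$value, n_par = 1L,
         rates = exp(opt$par))
  } else {
    opt <- stats::optim(rep(0, n_par), loglik_for, method = "L-BFGS-B",
                        lower = rep(log(1e-4), n_par),
                        upper = rep(log(1e4), n_par),
                        control = list(fnscale = -1, factr = 1e9))
    list(loglik = opt$value, n_par = n_par, rates = exp(opt$par))
  }
}

#' AIC weights from log-likelihoods and parameter counts
#'
#' `AIC = 2p - 2 lnL`; weights `w_i = exp(-Delta_i / 2)` normalized.
#'
#' @param loglik Numeric vector of maximized log-likelihoods.
#' @param n_par Integer vector of parameter counts.
#' @return Data frame `loglik`, `n_par`, `aic`, `delta_aic`, `weight`.
#' @export
aic_weights <- function(loglik, n_par) {
  aic <- 2 * n_par - 2 * loglik
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  data.frame(loglik = loglik, n_par = n_par, aic = aic, delta_aic = delta,
             weight = w / sum(w))
}

#' Rate-shift tests over branch/character partition schemes
#'
#' Fits each candidate scheme by maximizing the Mk likelihood with one rate
#' multiplier per partition block (branch lengths are `time x block rate`)
#' and compares schemes by AIC weight.  Missing cells are treated as equal
#' uncertainty over all states; inapplicable cells as missing.
#'
#' @param chronogram A `phylo` with time-calibrated branch lengths.
#' @param mm A [morph_matrix()].
#' @param schemes Named list; each element is a list with optional
#'   `edge_blocks` (block id per edge of the *postorder-reordered* tree,
#'   or a list of tip-label vectors whose spanned clades get their own
#'   block via [edge_blocks_from_clades()]) and `char_blocks` (block id
#'   per character).  `NULL` entries mean a single block.
#' @param model An [mk_model()] (rate multipliers absorb the overall rate,
#'   so `model$rate` is the fixed baseline).
#' @return A `rate_test_result` data frame: one row per scheme with
#'   `loglik`, `n_par`, `aic`, `delta_aic`, `weight`, plus fitted rates in
#'   attribute `fits`.
#' @export
test_rates <- function(chronogram, mm, schemes, model = mk_model(2)) {
  stopifnot(inherits(mm, "morph_matrix"), length(schemes) >= 1)
  tree <- ape::reorder.phylo(chronogram, "postorder")
  X <- .morph_as_int(mm)
  fits <- lapply(schemes, function(sc) {
    eb <- sc$edge_blocks
    if (is.list(eb)) eb <- edge_blocks_from_clades(tree, eb)
    .fit_rate_scheme(tree, X, model, eb, sc$char_blocks)
  })
  out <- aic_weights(vapply(fits, `[[`, numeric(1), "loglik"),
                     vapply(fits, `[[`, integer(1), "n_par"))
  out <- cbind(scheme = names(schemes), out)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("rate_test_result", class(out))
  out
}

#' Edge block ids from clade definitions
#'
#' Builds a per-edge block vector for [test_rates()]: edges whose child
#' lies within the i-th clade (the MRCA subtree of the given tips) get
#' block `i + 1`; all remaining edges form block 1.
#'
#' @param tree A `phylo` (postorder-reordered internally).
#' @param clades List of tip-label character vectors.
#' @param include_stem Include each clade's stem edge in its block
#'   (default `TRUE`).
#' @return Integer vector over edges of `reorder(tree, "postorder")`.
#' @export
edge_blocks_from_clades <- function(tree, clades, include_stem = TRUE) {
  tree <- ape::reorder.phylo(tree, "postorder")
  blocks <- rep(1L, nrow(tree$edge))
  for (i in seq_along(clades)) {
    tips <- match(clades[[i]], tree$tip.label)
    if (anyNA(tips)) stop("unknown tips in clade ", i)
    node <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    # collect all nodes in the subtree rooted at `node`
    sub <- node
    repeat {
      kids <- tree$edge[tree$edge[, 1] %in% sub, 2]
      new <- setdiff(kids, sub)
      if (!length(new)) break
      sub <- c(sub, new)
    }
    sel <- tree$edge[, 2] %in% sub
    if (!include_stem) sel <- sel & tree$edge[, 1] %in% sub
    blocks[sel] <- i + 1L
  }
  blocks
}
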