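# Implied character weights (homoplasy scores), guide-tree weight
# calibration, and 1-D k-means partitioning of the scores.

#' Implied weights of morphological characters on a tree
#'
#' Per character, extra steps `es = parsimony steps - (observed states - 1)`
#' and fit `f = k / (k + es)` with concavity constant `k`.  Characters
#' scored for fewer than two taxa get `NA` with a flag.
#'
#' @param mm A [morph_matrix()].
#' @param tree A `phylo` containing the scored taxa.
#' @param concavity Concavity constant `k` (> 0, default 3).
#' @return Data frame `character`, `steps`, `min_steps`, `extra_steps`,
#'   `fit`, `defined`.
#' @export
implied_weights <- function(mm, tree, concavity = 3) {
  stopifnot(concavity > 0)
  nch <- ncol(mm$mat)
  out <- data.frame(character = colnames(mm$mat), steps = NA_integer_,
                    min_steps = NA_integer_, extra_steps = NA_integer_,
                    fit = NA_real_, defined = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(nch)) {
    col <- .char_as_int(mm, j)
    scored <- col[!is.na(col)]
    scored <- scored[names(scored) %in% tree$tip.label]
    if (length(scored) < 2L) next
    steps <- parsimony_steps(tree, col, ordered = mm$ordered[j])
    min_steps <- length(unique(scored)) - 1L
    if (mm$ordered[j])
      min_steps <- max(scored) - min(scored)
    es <- steps - min_steps
    out$steps[j] <- steps
    out$min_steps[j] <- min_steps
    out$extra_steps[j] <- es
    out$fit[j] <- concavity / (concavity + es)
    out$defined[j] <- TRUE
  }
  out
}

#' Guide-tree calibrated character weights
#'
#' Implied-weight fits on a resolved guide tree, rescaled so the mean
#' weight over defined characters equals 1; undefined characters receive
#' weight 1.
#'
#' @inheritParams implied_weights
#' @param guide_tree Resolved `phylo` over the matrix taxa.
#' @return Numeric weight vector (one per character, mean 1 over defined
#'   characters), with the [implied_weights()] table as attribute `fits`.
#' @export
calibrate_weights <- function(mm, guide_tree, concavity = 3) {
  iw <- implied_weights(mm, guide_tree, concavity)
  w <- iw$fit
  mfit <- mean(w[iw$defined])
  if (!is.finite(mfit) || mfit == 0) stop("no defined character weights")
  w <- w / mfit
  w[!iw$defined] <- 1
  structure(w, fits = iw, names = iw$character)
}

#' Partition character scores by 1-D k-means with an elbow choice of k
#'
#' Runs [stats::kmeans()] for `k = 1..k_max` (25 restarts) on the score
#' vector and picks the k maximizing the second difference of the total
#' within-cluster sum of squares; an explicit `k_override` skips the elbow
#' rule.  Values of k exceeding the number of distinct scores are skipped.
#'
#' @param scores Numeric scores (e.g. implied-weight fits); `NA` allowed
#'   and left unassigned.
#' @param k_max Largest k tried (default 10).
#' @param seed Optional integer seed.
#' @param k_override Optional fixed k.
#' @param nstart Random restarts per k (default 25).
#' @return List with `k`, `clusters` (integer vector, `NA` where score was
#'   `NA`), `wss` (named per-k total within-cluster SS) and `centers`.
#' @export
partition_characters_kmeans <- function(scores, k_max = 10, seed = NULL,
                                        k_override = NULL, nstart = 25) {
  if (!is.null(seed)) set.seed(seed)
  ok <- which(!is.na(scores))
  x <- scores[ok]
  if (length(x) < 2L) stop("need >= 2 characters with finite scores")
  n_distinct <- length(unique(x))
  ks <- seq_len(min(k_max, length(x)))
  wss <- rep(NA_real_, length(ks)); names(wss) <- ks
  fits <- vector("list", length(ks))
  for (k in ks) {
    if (k > n_distinct) next
    if (k == 1L) {
      wss[k] <- sum((x - mean(x))^2)
      fits[[k]] <- list(cluster = rep(1L, length(x)), centers = mean(x))
    } else if (k == length(x)) {
      wss[k] <- 0
      fits[[k]] <- list(cluster = seq_along(x), centers = x)
    } else {
      km <- stats::kmeans(x, centers = k, nstart = nstart)
      wss[k] <- km$tot.withinss
      fits[[k]] <- km
    }
  }
  avail <- which(!is.na(wss))
  chosen <- if (!is.null(k_override)) {
    if (!(k_override %in% avail)) stop("k_override not attainable")
    k_override
  } else if (max(wss[avail]) < 1e-12) {
    1L
  } else if (length(avail) < 3L) {
    avail[which.min(wss[avail])]
  } else {
    # elbow: largest second difference of total within-SS
    d2 <- vapply(avail[-c(1, length(avail))], function(k)
      (wss[as.character(k - 1)] - wss[as.character(k)]) -
        (wss[as.character(k)] - wss[as.character(k + 1)]), numeric(1))
    avail[-c(1, length(avail))][which.max(d2)]
  }
  cl <- rep(NA_integer_, length(scores))
  cl[ok] <- fits[[chosen]]$cluster
  list(k = as.integer(chosen), clusters = cl, wss = wss[avail],
       centers = sort(unique(as.numeric(fits[[chosen]]$centers))))
}
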