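# Maximum Observable Rescaled Distance (MORD): a Gower-style morphological
# distance rescaled so every per-character dissimilarity lies in [0, 1].

#' MORD distance matrix of a morphological matrix
#'
#' For every taxon pair, per-character dissimilarity is computed over the
#' characters where both taxa are scored: `|a - b| / (max - min)` of the
#' character's states observed across the whole matrix for ordered
#' characters, and an inequality indicator for unordered ones.  The
#' pairwise distance is the mean per-character dissimilarity; pairs with no
#' comparable character are `NA`.
#'
#' @param mm A [morph_matrix()] with >= 2 taxa.
#' @param inapplicable `"exclude"` (default): `-` cells are non-comparable,
#'   like missing; `"missing"` is a synonym kept for clarity of intent.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
mord_distances <- function(mm, inapplicable = c("exclude", "missing")) {
  inapplicable <- match.arg(inapplicable)
  stopifnot(inherits(mm, "morph_matrix"))
  X <- .morph_as_int(mm)             # NA for both '?' and '-'
  n <- nrow(X)
  if (n < 2L) stop("need >= 2 taxa")
  nch <- ncol(X)
  rng <- vapply(seq_len(nch), function(j) {
    s <- X[, j][!is.na(X[, j])]
    if (!length(s)) return(1)
    max(1, max(s) - min(s))
  }, numeric(1))
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(X[i, ]) & !is.na(X[j, ])
    if (!any(ok)) { D[i, j] <- D[j, i] <- NA_real_; next }
    diffs <- abs(X[i, ok] - X[j, ok])
    dis <- ifelse(mm$ordered[ok], diffs / rng[ok], as.numeric(diffs > 0))
    D[i, j] <- D[j, i] <- mean(dis)
  }
  D
}

#' Per-taxon paired morphological vs molecular distance summary
#'
#' Summarizes each shared taxon as its mean pairwise distance to all other
#' shared taxa, in both tables, for scatter-plot comparison.
#'
#' @param morph_d,mol_d Symmetric distance matrices (or `dist` objects)
#'   with taxon labels.
#' @return Data frame `taxon`, `mean_morph`, `mean_mol` (one row per shared
#'   taxon).
#' @export
morpho_molecular_comparison <- function(morph_d, mol_d) {
  m1 <- as.matrix(morph_d); m2 <- as.matrix(mol_d)
  shared <- intersect(rownames(m1), rownames(m2))
  if (!length(shared)) stop("distance tables share no taxa")
  m1 <- m1[shared, shared, drop = FALSE]
  m2 <- m2[shared, shared, drop = FALSE]
  off <- function(m, i) mean(m[i, -i], na.rm = TRUE)
  data.frame(
    taxon = shared,
    mean_morph = vapply(seq_along(shared), function(i) off(m1, i), numeric(1)),
    mean_mol = vapply(seq_along(shared), function(i) off(m2, i), numeric(1)),
    stringsAsFactors = FALSE)
}
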