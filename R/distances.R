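# Pairwise maximum-likelihood molecular distances from the most complete
# genes, plus per-taxon averages for morphology-vs-molecule comparison.

# Closed-form ML distance under the symmetric k-state (Poisson) model:
# d = -((k-1)/k) * log(1 - k/(k-1) * p), with p the observed proportion of
# differing sites.  Saturated pairs (p >= (k-1)/k) return NA.
.poisson_ml_distance <- function(p, k) {
  lim <- (k - 1) / k
  out <- ifelse(p >= lim, NA_real_, -lim * log(1 - p / lim))
  out[p == 0] <- 0
  out
}

#' Pairwise maximum-likelihood distances from the most complete genes
#'
#' Selects the `top_k` genes with the highest occupancy, concatenates them,
#' and computes pairwise ML distances.  Under `model = "Poisson"` the
#' closed form for the symmetric k-state model is evaluated on the sites
#' where both sequences are scored; other amino-acid models (e.g. `"LG"`)
#' are delegated to [phangorn::dist.ml()].
#'
#' @param alignments List of `msa` gene alignments.
#' @param full_taxon_set All study taxa (for occupancy ranking); default
#'   the union over genes.
#' @param top_k Number of most-complete genes to use (default 50, capped at
#'   the number of genes).
#' @param model `"Poisson"` or an amino-acid model name understood by
#'   \pkg{phangorn} (e.g. `"LG"`, `"WAG"`).
#' @return List with `distances` (symmetric matrix, `NA` where a pair
#'   shares no scored site), `per_taxon` (named mean distance of each taxon
#'   to all others) and `genes_used`.
#' @export
pairwise_ml_distances <- function(alignments, full_taxon_set = NULL,
                                  top_k = 50, model = "Poisson") {
  if (!length(alignments)) stop("empty gene set")
  if (is.null(full_taxon_set))
    full_taxon_set <- unique(unlist(lapply(alignments, `[[`, "taxa")))
  occ <- vapply(alignments, occupancy, numeric(1), full_taxon_set)
  gn <- vapply(seq_along(alignments), function(i) {
    nm <- alignments[[i]]$name
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("gene", i)
    nm
  }, character(1))
  top_k <- min(top_k, length(alignments))
  keep <- order(-occ, gn)[seq_len(top_k)]
  sm <- build_supermatrix(alignments[keep], full_taxon_set = full_taxon_set)
  aln <- sm$alignment
  m <- as.matrix(aln)
  excl <- c("-", unknown_symbol(aln$alphabet))
  k <- length(alphabet_states(aln$alphabet))
  n <- nrow(m)
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  diag(D) <- 0
  if (identical(model, "Poisson")) {
    ok <- !(m %in% excl); dim(ok) <- dim(m)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      if (!any(use)) next
      p <- mean(m[i, use] != m[j, use])
      D[i, j] <- D[j, i] <- .poisson_ml_distance(p, k)
    }
  } else {
    if (aln$alphabet != "AA")
      stop("model '", model, "' requires amino-acid data")
    pd <- phangorn::phyDat(m, type = "AA")
    dm <- as.matrix(phangorn::dist.ml(pd, model = model))
    D[rownames(dm), colnames(dm)] <- dm
    diag(D) <- 0
  }
  per_taxon <- vapply(seq_len(n), function(i) mean(D[i, -i], na.rm = TRUE),
                      numeric(1))
  names(per_taxon) <- rownames(m)
  list(distances = D, per_taxon = per_taxon, genes_used = gn[keep])
}
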