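# Patterson's D (ABBA-BABA) with delete-one block-jackknife z-scores, and
# construction of per-family-combination four-taxon test matrices.

#' Four-taxon test specification
#'
#' Assumed topology `(((P1, P2), P3), O)`.
#'
#' @param p1,p2,p3,outgroup Distinct taxon ids.
#' @return A `quartet_spec` object.
#' @export
quartet_spec <- function(p1, p2, p3, outgroup) {
  taxa <- .normalize_taxa(c(p1, p2, p3, outgroup))
  if (anyDuplicated(taxa)) stop("the four taxa must be distinct")
  structure(list(p1 = taxa[1], p2 = taxa[2], p3 = taxa[3], outgroup = taxa[4]),
            class = "quartet_spec")
}

# Per-column classes for a quartet: 0 = unusable, 1 = informative other,
# 2 = ABBA, 3 = BABA.  Informative = all four residues scored and exactly
# two distinct states at the column.
.quartet_site_classes <- function(alignment, spec) {
  taxa <- c(spec$p1, spec$p2, spec$p3, spec$outgroup)
  miss <- setdiff(taxa, alignment$taxa)
  if (length(miss)) stop("taxa absent from matrix: ", paste(miss, collapse = ", "))
  m <- as.matrix(alignment)[taxa, , drop = FALSE]
  excl <- c("-", unknown_symbol(alignment$alphabet))
  scored <- colSums(matrix(m %in% excl, nrow = 4L)) == 0L
  anc <- m[4L, ]
  d1 <- m[1L, ] != anc; d2 <- m[2L, ] != anc; d3 <- m[3L, ] != anc
  # exactly two states: some row differs from the outgroup and all rows
  # that do carry one common derived state
  ok12 <- !d1 | !d2 | m[1L, ] == m[2L, ]
  ok13 <- !d1 | !d3 | m[1L, ] == m[3L, ]
  ok23 <- !d2 | !d3 | m[2L, ] == m[3L, ]
  inf <- scored & (d1 | d2 | d3) & ok12 & ok13 & ok23
  cls <- integer(ncol(m))
  cls[inf] <- 1L
  cls[inf & !d1 & d2 & d3] <- 2L  # ABBA
  cls[inf & d1 & !d2 & d3] <- 3L  # BABA
  cls
}

#' Count ABBA/BABA site patterns
#'
#' A site is informative when all four residues are scored (non-gap,
#' non-unknown) and exactly two distinct states occur; the outgroup state is
#' taken as ancestral.
#'
#' @param alignment An `msa` containing the four taxa.
#' @param spec A [quartet_spec()].
#' @return List with `n_abba`, `n_baba`, `n_informative`, `n_sites_scanned`.
#' @export
count_quartet_patterns <- function(alignment, spec) {
  cls <- .quartet_site_classes(alignment, spec)
  list(n_abba = sum(cls == 2L), n_baba = sum(cls == 3L),
       n_informative = sum(cls > 0L), n_sites_scanned = length(cls))
}

#' Patterson's D with a block-jackknife z-score
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`.  The standard error comes from a
#' delete-one jackknife over contiguous column blocks of `block_size`
#' columns (any trailing remainder is merged into the last block).
#'
#' @param alignment An `msa` containing the four taxa of `spec`.
#' @param spec A [quartet_spec()].
#' @param block_size Columns per jackknife block (default 1000).
#' @param z_threshold Absolute z-score called significant (default 3).
#' @return A `dstat_result` list: `D`, `se`, `z`, `n_blocks`, `counts`,
#'   `significant`.
#' @export
patterson_d <- function(alignment, spec, block_size = 1000, z_threshold = 3) {
  cls <- .quartet_site_classes(alignment, spec)
  nc <- length(cls)
  n_abba <- sum(cls == 2L); n_baba <- sum(cls == 3L)
  if (n_abba + n_baba < 1L) stop("no ABBA/BABA informative sites")
  nb <- nc %/% block_size
  if (nb < 2L) stop("need at least two jackknife blocks; reduce block_size")
  block <- pmin((seq_len(nc) - 1L) %/% block_size + 1L, nb)
  ab <- tabulate(block[cls == 2L], nb)
  bb <- tabulate(block[cls == 3L], nb)
  D <- (n_abba - n_baba) / (n_abba + n_baba)
  num_i <- (n_abba - ab) - (n_baba - bb)
  den_i <- (n_abba - ab) + (n_baba - bb)
  ok <- den_i > 0
  if (sum(ok) < 2L) stop("informative sites concentrated in a single block")
  d_i <- num_i[ok] / den_i[ok]
  g <- length(d_i)
  se <- sqrt((g - 1) / g * sum((d_i - mean(d_i))^2))
  z <- if (se > 0) D / se else if (D == 0) 0 else sign(D) * Inf
  structure(list(D = D, se = se, z = z, n_blocks = nb,
                 counts = list(n_abba = n_abba, n_baba = n_baba,
                               n_informative = sum(cls > 0L),
                               n_sites_scanned = nc),
                 significant = abs(z) >= z_threshold),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f (ABBA %d, BABA %d), z = %.2f over %d blocks%s\n",
              x$D, x$counts$n_abba, x$counts$n_baba, x$z, x$n_blocks,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Build all family-combination test matrices
#'
#' One concatenated four-taxon matrix per element of the Cartesian product
#' of three taxon groups, keeping only the genes where all four taxa
#' (including the fixed outgroup) are present and dropping all other rows.
#'
#' @param genes List of `msa` gene alignments.
#' @param groups List of three non-empty character vectors of taxon ids
#'   (roles P1, P2, P3 in order).
#' @param outgroup Outgroup taxon id (member of no group).
#' @return List of entries `list(spec, alignment, n_genes)`; combinations
#'   with no qualifying gene get `alignment = NULL`.
#' @export
enumerate_combination_matrices <- function(genes, groups, outgroup) {
  stopifnot(length(groups) == 3L)
  if (any(lengths(groups) == 0L)) stop("empty taxon group")
  groups <- lapply(groups, .normalize_taxa)
  outgroup <- .normalize_taxa(outgroup)
  if (outgroup %in% unlist(groups)) stop("outgroup must not belong to a group")
  if (anyDuplicated(unlist(groups))) stop("groups must be disjoint")
  combos <- expand.grid(p1 = groups[[1]], p2 = groups[[2]], p3 = groups[[3]],
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos))
  taxa_per_gene <- lapply(genes, `[[`, "taxa")
  for (i in seq_len(nrow(combos))) {
    four <- c(unlist(combos[i, ], use.names = FALSE), outgroup)
    spec <- quartet_spec(four[1], four[2], four[3], four[4])
    keep <- which(vapply(taxa_per_gene, function(tx) all(four %in% tx), logical(1)))
    if (!length(keep)) {
      out[[i]] <- list(spec = spec, alignment = NULL, n_genes = 0L)
      next
    }
    sub <- lapply(genes[keep], function(a)
      msa(a$seqs[four], alphabet = a$alphabet, name = a$name))
    sm <- build_supermatrix(sub, full_taxon_set = four)
    out[[i]] <- list(spec = spec, alignment = sm$alignment, n_genes = length(keep))
  }
  out
}

#' D-statistics for a set of combination matrices
#'
#' @param matrices Output of [enumerate_combination_matrices()].
#' @param block_size,z_threshold Passed to [patterson_d()].
#' @return Data frame, one row per combination with counts, D, z and the
#'   significance call (`NA` rows for combinations without data).
#' @export
dstat_table <- function(matrices, block_size = 1000, z_threshold = 3) {
  rows <- lapply(matrices, function(m) {
    base <- data.frame(p1 = m$spec$p1, p2 = m$spec$p2, p3 = m$spec$p3,
                       outgroup = m$spec$outgroup, n_genes = m$n_genes,
                       stringsAsFactors = FALSE)
    if (is.null(m$alignment))
      return(cbind(base, n_abba = NA, n_baba = NA, D = NA, z = NA,
                   significant = NA))
    r <- tryCatch(patterson_d(m$alignment, m$spec, block_size, z_threshold),
                  error = function(e) NULL)
    if (is.null(r))
      return(cbind(base, n_abba = NA, n_baba = NA, D = NA, z = NA,
                   significant = NA))
    cbind(base, n_abba = r$counts$n_abba, n_baba = r$counts$n_baba,
          D = r$D, z = r$z, significant = r$significant)
  })
  do.call(rbind, rows)
}
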