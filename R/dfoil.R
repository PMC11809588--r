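# Five-taxon D-FOIL-style statistics on the symmetric topology
# ((P1,P2),(P3,P4),O).  Four null-balanced statistics are formed from the
# cross-pair derived-sharing site patterns; their joint sign signature
# identifies which taxa exchanged genes.
#
# Patterns are written as P1 P2 P3 P4 states relative to the outgroup
# (A = ancestral, B = derived); only biallelic, fully scored columns count.
# The four sharing patterns are
#   BABA (P1,P3), ABBA (P2,P3), BAAB (P1,P4), ABAB (P2,P4).
# Under the species topology P1/P2 are exchangeable, as are P3/P4, so all
# four have equal expectation and each statistic below has expectation zero
# without gene flow:
#   DFO = (BABA - ABAB) / (BABA + ABAB)   P1-P3 vs P2-P4 sharing
#   DIL = (ABBA - BAAB) / (ABBA + BAAB)   P2-P3 vs P1-P4 sharing
#   DFI = (BABA + BAAB - ABBA - ABAB) / total   which first-pair taxon
#   DOL = (BABA + ABBA - BAAB - ABAB) / total   which second-pair taxon
# Relabelling symmetries: swapping P1/P2 exchanges DFO with DIL, negates
# DFI and leaves DOL; swapping P3/P4 maps DFO to -DIL, negates DOL and
# leaves DFI.

#' Five-taxon test specification
#'
#' Assumed symmetric topology `((P1,P2),(P3,P4),O)` with the (P1,P2) split
#' younger than the (P3,P4) split.
#'
#' @param p1,p2,p3,p4,outgroup Distinct taxon ids.
#' @return A `dfoil_spec` object.
#' @export
dfoil_spec <- function(p1, p2, p3, p4, outgroup) {
  taxa <- .normalize_taxa(c(p1, p2, p3, p4, outgroup))
  if (anyDuplicated(taxa)) stop("the five taxa must be distinct")
  structure(list(p1 = taxa[1], p2 = taxa[2], p3 = taxa[3], p4 = taxa[4],
                 outgroup = taxa[5]), class = "dfoil_spec")
}

#' Count the 16 biallelic five-taxon site patterns
#'
#' @param alignment An `msa` containing the five taxa.
#' @param spec A [dfoil_spec()].
#' @return List with `patterns` (named 16-vector, names `AAAA`..`BBBB` for
#'   the P1..P4 states with the outgroup ancestral), `n_informative` and
#'   `n_sites_scanned`.
#' @export
count_quintet_patterns <- function(alignment, spec) {
  taxa <- c(spec$p1, spec$p2, spec$p3, spec$p4, spec$outgroup)
  miss <- setdiff(taxa, alignment$taxa)
  if (length(miss)) stop("taxa absent from matrix: ", paste(miss, collapse = ", "))
  m <- as.matrix(alignment)[taxa, , drop = FALSE]
  excl <- c("-", unknown_symbol(alignment$alphabet))
  scored <- colSums(matrix(m %in% excl, nrow = 5L)) == 0L
  anc0 <- m[5L, ]
  dvd <- m[1:4, , drop = FALSE] != rep(anc0, each = 4L)
  shared_ok <- rep(TRUE, ncol(m))
  for (i in 1:3) for (j in (i + 1):4)
    shared_ok <- shared_ok &
      (!dvd[i, ] | !dvd[j, ] | m[i, ] == m[j, ])
  inf <- scored & colSums(dvd) > 0L & shared_ok
  anc <- m[5L, inf]
  bits <- (m[1:4, inf, drop = FALSE] != rep(anc, each = 4L)) + 0L
  idx <- 8L * bits[1, ] + 4L * bits[2, ] + 2L * bits[3, ] + bits[4, ]
  nm <- vapply(0:15, function(i)
    paste(c("A", "B")[1 + c(i %/% 8, i %/% 4 %% 2, i %/% 2 %% 2, i %% 2)],
          collapse = ""), character(1))
  counts <- stats::setNames(tabulate(idx + 1L, 16L), nm)
  list(patterns = counts, n_informative = sum(inf),
       n_sites_scanned = ncol(m))
}

.dfoil_terms <- list(
  DFO = list(left = "BABA", right = "ABAB"),
  DIL = list(left = "ABBA", right = "BAAB"),
  DFI = list(left = c("BABA", "BAAB"), right = c("ABBA", "ABAB")),
  DOL = list(left = c("BABA", "ABBA"), right = c("BAAB", "ABAB"))
)

# Sign-signature table over (DFI, DOL): DOL says which of P3/P4 is
# involved, DFI which of P1/P2; DFI = 0 with DOL significant indicates gene
# flow involving the (P1,P2) ancestral lineage.
.dfoil_classes <- c(
  "+/+" = "P1<->P3", "-/+" = "P2<->P3",
  "+/-" = "P1<->P4", "-/-" = "P2<->P4",
  "0/+" = "ancestral(P1,P2)<->P3", "0/-" = "ancestral(P1,P2)<->P4",
  "0/0" = "none"
)

#' D-FOIL-style introgression statistics for a five-taxon matrix
#'
#' Computes the four statistics described in the package's methods vignette,
#' tests each with a two-sided binomial test of its left against right
#' pattern totals, and maps the joint sign signature to an introgression
#' class.
#'
#' @param alignment An `msa` containing the five taxa.
#' @param spec A [dfoil_spec()].
#' @param min_informative Minimum informative sites; below this an
#'   "insufficient data" result is returned with no class (default 100).
#' @param alpha Per-statistic significance level (default 0.01).
#' @return A `dfoil_result` list: `stats` (named 4-vector), `p_values`,
#'   `signature` (string of `+`/`-`/`0`), `class`, `counts`.
#' @export
dfoil <- function(alignment, spec, min_informative = 100, alpha = 0.01) {
  pc <- count_quintet_patterns(alignment, spec)
  n <- pc$patterns
  vals <- p <- stats::setNames(numeric(4), names(.dfoil_terms))
  for (s in names(.dfoil_terms)) {
    L <- sum(n[.dfoil_terms[[s]]$left]); R <- sum(n[.dfoil_terms[[s]]$right])
    vals[s] <- if (L + R > 0) (L - R) / (L + R) else 0
    p[s] <- if (L + R > 0)
      stats::binom.test(L, L + R, 0.5, alternative = "two.sided")$p.value else 1
  }
  if (pc$n_informative < min_informative) {
    return(structure(list(stats = vals, p_values = p, signature = NA_character_,
                          class = "insufficient data", counts = pc),
                     class = "dfoil_result"))
  }
  sig <- ifelse(p < alpha, ifelse(vals > 0, "+", "-"), "0")
  key <- paste(sig["DFI"], sig["DOL"], sep = "/")
  cls <- if (key == "0/0") {
    if (all(sig == "0")) "none" else "unclassified"
  } else if (!is.na(.dfoil_classes[key])) unname(.dfoil_classes[key])
    else "unclassified"
  structure(list(stats = vals, p_values = p,
                 signature = paste(sig, collapse = ""), class = cls,
                 counts = pc),
            class = "dfoil_result")
}

#' @export
print.dfoil_result <- function(x, ...) {
  cat(sprintf("DFO %.3f  DIL %.3f  DFI %.3f  DOL %.3f  [%s] -> %s\n",
              x$stats["DFO"], x$stats["DIL"], x$stats["DFI"], x$stats["DOL"],
              if (is.na(x$signature)) "----" else x$signature, x$class))
  invisible(x)
}
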