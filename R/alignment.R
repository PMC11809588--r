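# Multiple alignments: a light container over named residue strings.
# Residues are stored upper-case; gap is '-', unknown is 'X' (AA) or 'N' (DNA).

#' Residue states of an alphabet
#'
#' @param alphabet `"AA"` or `"DNA"`.
#' @return Character vector of core states (no gap/unknown symbol).
#' @export
alphabet_states <- function(alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  switch(alphabet,
    AA  = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    DNA = c("A", "C", "G", "T")
  )
}

#' Unknown-residue symbol of an alphabet
#' @inheritParams alphabet_states
#' @return `"X"` for amino acids, `"N"` for nucleotides.
#' @export
unknown_symbol <- function(alphabet = c("AA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "AA") "X" else "N"
}

.normalize_taxa <- function(x) gsub("[[:space:]]+", "_", trimws(x))

#' Construct a multiple alignment
#'
#' Builds an `msa` object from named, equal-length residue strings.  Taxon
#' ids are normalized (whitespace becomes underscore) and residues are
#' upper-cased.  Residues outside the alphabet that are not the gap symbol
#' are remapped to the unknown symbol with a warning, so that rare
#' ambiguity codes in transcriptome-derived proteins do not abort a run.
#'
#' @param seqs Named character vector of aligned residue strings.
#' @param alphabet `"AA"` or `"DNA"`.
#' @param name Optional alignment (gene) name.
#' @return An object of class `msa` with elements `name`, `taxa`, `seqs`
#'   (named character vector) and `alphabet`.
#' @export
msa <- function(seqs, alphabet = c("AA", "DNA"), name = NULL) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named with taxon ids")
  taxa <- .normalize_taxa(names(seqs))
  dup <- taxa[duplicated(taxa)]
  if (length(dup))
    stop("duplicate taxon id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(seqs))
  names(seqs) <- taxa
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("ragged alignment: row lengths ", paste(sort(len), collapse = ", "))
  ok <- c(alphabet_states(alphabet), "-", unknown_symbol(alphabet))
  all_chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(all_chars, ok)
  if (length(bad)) {
    warning("remapping ", length(bad), " symbol(s) outside the ", alphabet,
            " alphabet to '", unknown_symbol(alphabet), "': ",
            paste(bad, collapse = " "))
    for (b in bad) seqs <- gsub(b, unknown_symbol(alphabet), seqs, fixed = TRUE)
  }
  structure(list(name = name, taxa = taxa, seqs = seqs, alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa", if (!is.null(x$name)) paste0("'", x$name, "'") else "", "> ",
      length(x$taxa), " taxa x ", msa_length(x), " ", x$alphabet,
      " columns\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param x An `msa`.
#' @return Integer column count.
#' @export
msa_length <- function(x) {
  stopifnot(inherits(x, "msa"))
  if (length(x$seqs) == 0L) return(0L)
  nchar(x$seqs[[1]])
}

#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$taxa
  m
}

#' Build an alignment from a character matrix
#' @param m Character matrix with taxon rownames, one residue per cell.
#' @inheritParams msa
#' @return An `msa`.
#' @export
msa_from_matrix <- function(m, alphabet = c("AA", "DNA"), name = NULL) {
  seqs <- apply(m, 1L, paste, collapse = "")
  msa(seqs, alphabet = alphabet, name = name)
}

#' Read an aligned FASTA or relaxed PHYLIP file
#'
#' The format is auto-detected: files starting with `>` are parsed as FASTA
#' (via \pkg{seqinr}), anything else as relaxed sequential PHYLIP
#' (`ntax nchar` header, then one `name sequence` record per line).
#'
#' @param path File path.
#' @param alphabet `"AA"` or `"DNA"`.
#' @param name Optional gene name; defaults to the file base name.
#' @return An `msa`; input row order is preserved.
#' @export
read_alignment <- function(path, alphabet = c("AA", "DNA"), name = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(trimws(first), ">")) {
    recs <- seqinr::read.fasta(path, seqtype = if (alphabet == "AA") "AA" else "DNA",
                               as.string = TRUE, set.attributes = FALSE,
                               forceDNAtolower = FALSE)
    seqs <- unlist(recs, use.names = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
    if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
      stop("not a PHYLIP header: '", lines[1], "'")
    ntax <- as.integer(hdr[1])
    if (length(lines) - 1L < ntax)
      stop("PHYLIP file declares ", ntax, " taxa but has ",
           length(lines) - 1L, " records")
    toks <- strsplit(trimws(lines[2:(ntax + 1L)]), "[[:space:]]+")
    seqs <- vapply(toks, function(t) paste(t[-1], collapse = ""), character(1))
    names(seqs) <- vapply(toks, `[[`, character(1), 1L)
  }
  msa(seqs, alphabet = alphabet, name = name)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#'
#' @param x An `msa`.
#' @param path Output path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(x, path, format = c("fasta", "phylip")) {
  stopifnot(inherits(x, "msa"))
  format <- match.arg(format)
  if (format == "fasta") {
    out <- character(2L * length(x$taxa))
    out[c(TRUE, FALSE)] <- paste0(">", x$taxa)
    out[c(FALSE, TRUE)] <- unname(x$seqs)
  } else {
    out <- c(paste(length(x$taxa), msa_length(x)),
             paste(x$taxa, unname(x$seqs)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa missing from a gene are filled with the gap symbol over that gene's
#' block.  Per-taxon non-gap residue counts are conserved by construction.
#'
#' @param alignments List of `msa` objects sharing one alphabet.  Gene names
#'   are taken from each `msa`'s `name` (list names as fallback) and must be
#'   unique.
#' @param full_taxon_set Character vector of taxa spanning the supermatrix;
#'   defaults to the union over genes.
#' @return A list with `alignment` (the concatenated `msa`) and `partitions`
#'   (data frame `gene`, `start`, `end`; 1-based inclusive, input order).
#' @export
build_supermatrix <- function(alignments, full_taxon_set = NULL) {
  if (!length(alignments)) stop("no alignments supplied")
  stopifnot(all(vapply(alignments, inherits, logical(1), "msa")))
  alpha <- unique(vapply(alignments, `[[`, character(1), "alphabet"))
  if (length(alpha) != 1L) stop("alignments mix alphabets: ",
                                paste(alpha, collapse = ", "))
  gn <- vapply(seq_along(alignments), function(i) {
    nm <- alignments[[i]]$name
    if (is.null(nm) || !nzchar(nm)) nm <- names(alignments)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("gene", i)
    nm
  }, character(1))
  if (anyDuplicated(gn))
    stop("duplicate gene name(s): ", paste(unique(gn[duplicated(gn)]), collapse = ", "))
  if (is.null(full_taxon_set))
    full_taxon_set <- unique(unlist(lapply(alignments, `[[`, "taxa")))
  full_taxon_set <- .normalize_taxa(full_taxon_set)
  extra <- setdiff(unlist(lapply(alignments, `[[`, "taxa")), full_taxon_set)
  if (length(extra))
    stop("taxa not in full_taxon_set: ", paste(unique(extra), collapse = ", "))
  lens <- vapply(alignments, msa_length, integer(1))
  blocks <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    s <- a$seqs[full_taxon_set]
    s[is.na(s)] <- strrep("-", lens[i])
    unname(s)
  })
  seqs <- do.call(paste0, blocks)
  names(seqs) <- full_taxon_set
  ends <- cumsum(lens)
  parts <- data.frame(gene = gn, start = c(1L, utils::head(ends, -1L) + 1L),
                      end = ends, stringsAsFactors = FALSE)
  list(alignment = msa(seqs, alphabet = alpha, name = "supermatrix"),
       partitions = parts)
}

#' Write a RAxML-style partition file
#'
#' One line per block: `MODEL, name = start-end` (1-based inclusive).
#'
#' @param partitions Data frame with `gene`, `start`, `end` as returned by
#'   [build_supermatrix()].
#' @param path Output path.
#' @param model Substitution model label to print (default `"LG"`).
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path, model = "LG") {
  writeLines(sprintf("%s, %s = %d-%d", model, partitions$gene,
                     partitions$start, partitions$end), path)
  invisible(path)
}

#' Read a taxon-to-group (family) membership table
#'
#' Two tab-separated columns, taxon then group; lines starting with `#` and
#' an optional `taxon<TAB>group` header are skipped.
#'
#' @param path File path.
#' @return Named character vector mapping taxon id to group label.
#' @export
read_group_map <- function(path) {
  d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("group map needs two tab-separated columns")
  if (tolower(d[1, 1]) %in% c("taxon", "species", "id")) d <- d[-1, , drop = FALSE]
  taxa <- .normalize_taxa(d[[1]])
  if (anyDuplicated(taxa))
    stop("taxon mapped more than once: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  stats::setNames(as.character(d[[2]]), taxa)
}
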