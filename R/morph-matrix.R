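# Discrete morphological matrices and their NEXUS representation.
# Cells hold a single state symbol, '?' (missing) or '-' (inapplicable).

#' Construct a morphological character matrix
#'
#' @param mat Character matrix, taxa in rows (rownames required), characters
#'   in columns.  Cells are single state symbols drawn from `symbols`, `"?"`
#'   for missing or `"-"` for inapplicable.
#' @param ordered Logical vector, one flag per character (default all
#'   unordered).
#' @param weights Non-negative numeric vector of per-character weights
#'   (default 1).
#' @param symbols Allowed state symbols (default `"0"`--`"9"`).
#' @return An object of class `morph_matrix` with elements `mat`, `ordered`,
#'   `weights`, `symbols`.
#' @export
morph_matrix <- function(mat, ordered = NULL, weights = NULL,
                         symbols = as.character(0:9)) {
  if (is.null(rownames(mat))) stop("mat needs taxon rownames")
  mat <- as.matrix(mat)
  mode(mat) <- "character"
  rownames(mat) <- .normalize_taxa(rownames(mat))
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon id(s) in morphological matrix")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
  nch <- ncol(mat)
  if (is.null(ordered)) ordered <- rep(FALSE, nch)
  if (is.null(weights)) weights <- rep(1, nch)
  stopifnot(length(ordered) == nch, length(weights) == nch,
            all(is.finite(weights)), all(weights >= 0))
  bad_flag <- !(mat %in% c(symbols, "?", "-"))
  dim(bad_flag) <- dim(mat)
  bad <- which(bad_flag, arr.ind = TRUE)
  if (nrow(bad))
    stop("state symbol '", mat[bad[1, 1], bad[1, 2]], "' outside SYMBOLS at row ",
         bad[1, 1], " (", rownames(mat)[bad[1, 1]], "), character ", bad[1, 2])
  structure(list(mat = mat, ordered = as.logical(ordered),
                 weights = as.numeric(weights), symbols = symbols),
            class = "morph_matrix")
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat("<morph_matrix> ", nrow(x$mat), " taxa x ", ncol(x$mat), " characters (",
      sum(x$ordered), " ordered; ", sum(x$mat == "?"), " missing, ",
      sum(x$mat == "-"), " inapplicable cells)\n", sep = "")
  invisible(x)
}

#' @export
dim.morph_matrix <- function(x) dim(x$mat)

# Integer view of one character: 0-based states, NA for '?' and (optionally)
# '-'.  Inapplicable is treated as missing for likelihood/parsimony work.
.char_as_int <- function(mm, j) {
  v <- mm$mat[, j]
  out <- match(v, mm$symbols) - 1L
  names(out) <- rownames(mm$mat)
  out
}

# Full integer matrix (taxa x characters), NA = missing/inapplicable.
.morph_as_int <- function(mm) {
  out <- matrix(match(mm$mat, mm$symbols) - 1L, nrow = nrow(mm$mat),
                dimnames = dimnames(mm$mat))
  out
}

.strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", " ", txt)

#' Read a morphological matrix from a NEXUS file
#'
#' Parses the `CHARACTERS` (or `DATA`) block: `DIMENSIONS`, `FORMAT`
#' (`SYMBOLS`, `MISSING`, `GAP`) and `MATRIX`.  An optional `ASSUMPTIONS`
#' block `TYPESET` line (`ord: <ranges>` / `unord: <ranges>`) sets the
#' per-character ordered flags; characters default to unordered.  `?` maps
#' to missing and the gap symbol to inapplicable.  Polymorphic cells
#' (`(01)`-style) are recoded as missing with a warning.
#'
#' @param path File path.
#' @return A [morph_matrix()].
#' @export
read_morph_nexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) stop("not a NEXUS file: ", path)
  txt <- .strip_nexus_comments(txt)
  up <- toupper(txt)
  blk <- regmatches(txt, regexpr("(?is)BEGIN\\s+(CHARACTERS|DATA)\\s*;.*?END\\s*;",
                                 txt, perl = TRUE))
  if (!length(blk)) stop("no CHARACTERS/DATA block found")
  blk <- blk[[1]]

  dimln <- regmatches(blk, regexpr("(?i)DIMENSIONS[^;]*;", blk, perl = TRUE))
  ntax <- as.integer(sub(".*(?i)NTAX\\s*=\\s*(\\d+).*", "\\1", dimln, perl = TRUE))
  nchr <- as.integer(sub(".*(?i)NCHAR\\s*=\\s*(\\d+).*", "\\1", dimln, perl = TRUE))

  fmtln <- regmatches(blk, regexpr("(?i)FORMAT[^;]*;", blk, perl = TRUE))
  symbols <- as.character(0:9)
  missing_sym <- "?"; gap_sym <- "-"
  if (length(fmtln)) {
    sm <- regmatches(fmtln, regexpr('(?i)SYMBOLS\\s*=\\s*"[^"]*"', fmtln, perl = TRUE))
    if (length(sm)) {
      s <- sub('.*"([^"]*)".*', "\\1", sm)
      symbols <- setdiff(strsplit(s, "")[[1]], " ")
    }
    mm_ <- regmatches(fmtln, regexpr("(?i)MISSING\\s*=\\s*\\S", fmtln, perl = TRUE))
    if (length(mm_)) missing_sym <- substr(mm_, nchar(mm_), nchar(mm_))
    gm <- regmatches(fmtln, regexpr("(?i)GAP\\s*=\\s*\\S", fmtln, perl = TRUE))
    if (length(gm)) gap_sym <- substr(gm, nchar(gm), nchar(gm))
  }

  mx <- regmatches(blk, regexpr("(?is)MATRIX(.*?);", blk, perl = TRUE))
  if (!length(mx)) stop("no MATRIX section found")
  body <- sub("(?is)^MATRIX", "", mx, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(body, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  taxa <- character(0); cells <- list()
  for (r in rows) {
    if (startsWith(r, "'")) {
      nm <- sub("^'([^']*)'.*", "\\1", r)
      rest <- trimws(sub("^'[^']*'", "", r))
    } else {
      nm <- sub("^(\\S+).*", "\\1", r)
      rest <- trimws(sub("^\\S+", "", r))
    }
    states <- character(0)
    chars <- strsplit(gsub("[[:space:]]", "", rest), "")[[1]]
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] %in% c("(", "{")) {
        j <- i
        while (j <= length(chars) && !(chars[j] %in% c(")", "}"))) j <- j + 1L
        states <- c(states, "POLY")
        i <- j + 1L
      } else {
        states <- c(states, chars[i])
        i <- i + 1L
      }
    }
    taxa <- c(taxa, nm)
    cells[[length(cells) + 1L]] <- states
  }
  if (!is.na(ntax) && length(taxa) != ntax)
    stop("MATRIX has ", length(taxa), " taxa, DIMENSIONS declares ", ntax)
  lens <- lengths(cells)
  if (length(unique(lens)) != 1L)
    stop("ragged MATRIX rows (", paste(unique(lens), collapse = ", "), " characters)")
  if (!is.na(nchr) && lens[1] != nchr)
    stop("MATRIX rows have ", lens[1], " characters, DIMENSIONS declares ", nchr)
  m <- do.call(rbind, cells)
  rownames(m) <- taxa
  npoly <- sum(m == "POLY")
  if (npoly) {
    warning(npoly, " polymorphic cell(s) recoded as missing")
    m[m == "POLY"] <- "?"
  }
  m[m == missing_sym] <- "?"
  m[m == gap_sym] <- "-"

  ordered <- rep(FALSE, ncol(m))
  ts <- regmatches(txt, regexpr("(?i)TYPESET[^;]*;", txt, perl = TRUE))
  if (length(ts)) {
    spec <- sub(".*=", "", sub(";\\s*$", "", ts))
    for (grp in strsplit(spec, ",")[[1]]) {
      kv <- strsplit(grp, ":")[[1]]
      if (length(kv) != 2L) next
      type <- tolower(trimws(kv[1]))
      idx <- unlist(lapply(strsplit(trimws(kv[2]), "[[:space:]]+")[[1]], function(tok) {
        if (grepl("-", tok)) {
          ab <- as.integer(strsplit(tok, "-")[[1]])
          seq(ab[1], ab[2])
        } else as.integer(tok)
      }))
      if (type %in% c("ord", "ordered")) ordered[idx] <- TRUE
      if (type %in% c("unord", "unordered")) ordered[idx] <- FALSE
    }
  }
  morph_matrix(m, ordered = ordered, symbols = symbols)
}

#' Write a morphological matrix as NEXUS
#'
#' Emits a `CHARACTERS` block (`MISSING=?`, `GAP=-`) and, when any character
#' is flagged ordered, an `ASSUMPTIONS` block with a `TYPESET` line.
#'
#' @param x A [morph_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morph_nexus <- function(x, path) {
  stopifnot(inherits(x, "morph_matrix"))
  m <- x$mat
  rows <- paste(format(rownames(m), width = max(nchar(rownames(m)))),
                apply(m, 1L, paste, collapse = ""))
  out <- c("#NEXUS", "", "BEGIN CHARACTERS;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
           sprintf('  FORMAT DATATYPE=STANDARD SYMBOLS="%s" MISSING=? GAP=-;',
                   paste(x$symbols, collapse = " ")),
           "  MATRIX", paste0("    ", rows), "  ;", "END;")
  if (any(x$ordered)) {
    ord <- paste(which(x$ordered), collapse = " ")
    unord <- paste(which(!x$ordered), collapse = " ")
    line <- if (any(!x$ordered))
      sprintf("  TYPESET * default = ord: %s, unord: %s;", ord, unord)
    else sprintf("  TYPESET * default = ord: %s;", ord)
    out <- c(out, "", "BEGIN ASSUMPTIONS;", line, "END;")
  }
  writeLines(out, path)
  invisible(path)
}
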