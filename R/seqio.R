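# Sequence and alignment I/O, IUPAC alphabet handling, coordinate conventions.
#
# Internal coordinates are 0-based half-open throughout the package; anything
# user-facing (hit tables, alignments) is 1-based inclusive, with minus-strand
# hits reported from > to.

# IUPAC nucleotide codes in the fixed order used by the DP kernels.
IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

# Compatibility sets: which of A,C,G,T each code can stand for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Complement table over the full degenerate alphabet.
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' DNA sequence record
#'
#' A lightweight container for a named DNA sequence together with the
#' coordinate bookkeeping needed when the sequence is a window cut out of a
#' longer parent sequence: `source_offset` is the 0-based offset of the first
#' residue within the parent, and `strand` records which strand of the parent
#' the residues came from.
#'
#' @param id Sequence identifier.
#' @param residues Character scalar over the IUPAC DNA alphabet (stored
#'   uppercase; `U` is mapped to `T`).
#' @param description Free-text description (rest of the FASTA header).
#' @param source_offset 0-based offset within the parent sequence.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, description = "", source_offset = 0L,
                       strand = "+") {
  residues <- sanitize_dna(residues, context = id)
  stopifnot(source_offset >= 0, strand %in% c("+", "-"))
  structure(
    list(id = as.character(id), description = as.character(description),
         residues = residues, source_offset = as.integer(source_offset),
         strand = strand),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  head <- substr(x$residues, 1L, 60L)
  cat(sprintf("seq_record %s [%d nt, %s strand, offset %d]\n%s%s\n",
              x$id, n, x$strand, x$source_offset, head,
              if (n > 60L) "..." else ""))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

# Uppercase, U->T, validate against the IUPAC alphabet. Returns the cleaned
# string; errors name the offending character and (if given) the context.
sanitize_dna <- function(s, context = NULL, line = NULL) {
  s <- chartr("u", "t", toupper(s))
  s <- chartr("U", "T", s)
  bad <- stringi::stri_locate_first_regex(s, "[^ACGTRYSWKMBDHVN]")[1, 1]
  if (!is.na(bad)) {
    where <- if (!is.null(line)) sprintf(" at line %d", line)
             else if (!is.null(context)) sprintf(" in '%s'", context) else ""
    stop(sprintf("non-IUPAC nucleotide character '%s'%s (position %d)",
                 substr(s, bad, bad), where, bad), call. = FALSE)
  }
  s
}

#' Read a FASTA file of DNA sequences
#'
#' One `seq_record` per header, in file order. Residues are uppercased and `U`
#' is mapped to `T`. Duplicate ids are allowed but produce a warning. An empty
#' file yields an empty list. Malformed headers or non-IUPAC characters raise
#' a parse error naming the line number.
#'
#' @param path Path to a FASTA file.
#' @return List of [seq_record] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 0L]
  if (length(lines) == 0L) return(list())
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) {
    stop(sprintf("FASTA parse error at line 1: expected '>' header, got '%s'",
                 substr(lines[1L], 1, 30)), call. = FALSE)
  }
  idx <- which(hdr)
  recs <- vector("list", length(idx))
  ids <- character(length(idx))
  bounds <- c(idx, length(lines) + 1L)
  for (j in seq_along(idx)) {
    h <- sub("^>", "", lines[idx[j]])
    id <- sub("\\s.*$", "", h)
    if (!nzchar(id)) {
      stop(sprintf("FASTA parse error at line %d: empty sequence id", idx[j]),
           call. = FALSE)
    }
    desc <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    body <- lines[seq.int(idx[j] + 1L, bounds[j + 1L] - 1L, length.out =
                            max(0L, bounds[j + 1L] - idx[j] - 1L))]
    seq <- paste(gsub("\\s", "", body), collapse = "")
    # locate the line for error reporting before sanitizing the whole body
    cleaned <- tryCatch(sanitize_dna(seq), error = function(e) e)
    if (inherits(cleaned, "error")) {
      for (bi in seq_along(body)) {
        t <- tryCatch(sanitize_dna(gsub("\\s", "", body[bi]),
                                   line = idx[j] + bi),
                      error = function(e) e)
        if (inherits(t, "error")) stop(t)
      }
      stop(cleaned)
    }
    ids[j] <- id
    recs[[j]] <- seq_record(id, cleaned, description = desc)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    warning("duplicate sequence id(s) in ", path, ": ",
            paste(dup, collapse = ", "), call. = FALSE)
  }
  recs
}

#' Write sequences to a FASTA file
#'
#' Sequences are wrapped at 60 columns. `read_fasta(write_fasta(x))` is an
#' identity up to line wrapping.
#'
#' @param records List of [seq_record] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste0(">", r$id, " ", r$description)
           else paste0(">", r$id)
    writeLines(hdr, con)
    n <- nchar(r$residues)
    if (n > 0L) {
      starts <- seq.int(1L, n, by = width)
      writeLines(substring(r$residues, starts,
                           pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(NULL)
}

#' Reverse complement of an IUPAC DNA string
#'
#' Degenerate codes are complemented per IUPAC (R<->Y, K<->M, B<->V, D<->H,
#' S, W, N self-complementary).
#'
#' @param s DNA string (IUPAC alphabet, case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(s) {
  s <- sanitize_dna(s)
  stringi::stri_reverse(chartr(IUPAC_FROM, IUPAC_TO, s))
}

#' Multiple DNA sequence alignment
#'
#' Ordered rows of equal-length aligned strings. Both `-` and `.` are accepted
#' as gap symbols on input and normalized to `-`.
#'
#' @param ids Character vector of unique row ids.
#' @param seqs Character vector of aligned strings (equal lengths).
#' @param rf Optional reference-column annotation string (e.g. a Stockholm
#'   `#=GC RF` line), same length as the rows.
#' @return An object of class `msa`.
#' @export
msa <- function(ids, seqs, rf = NULL) {
  stopifnot(length(ids) == length(seqs), length(ids) >= 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate row ids in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(chartr(".", "-", seqs))
  nc <- unique(nchar(seqs))
  if (length(nc) != 1L) {
    bad <- ids[nchar(seqs) != nchar(seqs)[1L]][1L]
    stop(sprintf("ragged alignment: row '%s' has a different length", bad),
         call. = FALSE)
  }
  for (i in seq_along(seqs)) {
    nogap <- gsub("-", "", seqs[i])
    if (nzchar(nogap)) sanitize_dna(nogap, context = ids[i])
  }
  if (!is.null(rf) && nchar(rf) != nc) {
    stop("RF annotation length does not match alignment columns", call. = FALSE)
  }
  structure(list(ids = as.character(ids), seqs = seqs,
                 n_columns = as.integer(nc), rf = rf),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows x %d columns\n", length(x$ids), x$n_columns))
  invisible(x)
}

# alignment as a character matrix (rows x columns)
msa_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}

#' Read a multiple sequence alignment
#'
#' Supports Stockholm (`format = "stockholm"`) and aligned FASTA
#' (`format = "afa"`). A Stockholm `#=GC RF` line, if present, is captured as
#' the `rf` column annotation.
#'
#' @param path Input path.
#' @param format `"stockholm"` or `"afa"`.
#' @return An [msa] object.
#' @export
read_msa <- function(path, format = c("stockholm", "afa")) {
  format <- match.arg(format)
  if (format == "afa") {
    recs <- read_fasta_aligned(path)
    return(msa(vapply(recs, `[[`, "", "id"),
               vapply(recs, `[[`, "", "seq")))
  }
  lines <- readLines(path, warn = FALSE)
  ids <- character(); seqs <- list(); rf <- character()
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || grepl("^//", ln)) next
    if (grepl("^#=GC\\s+RF\\s", ln)) {
      rf <- c(rf, sub("^#=GC\\s+RF\\s+", "", ln))
      next
    }
    if (grepl("^#", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) {
      stop("Stockholm parse error: expected 'id sequence', got: ",
           substr(ln, 1, 40), call. = FALSE)
    }
    id <- parts[1L]
    j <- match(id, ids)
    if (is.na(j)) {
      ids <- c(ids, id)
      seqs[[length(seqs) + 1L]] <- parts[2L]
    } else {
      seqs[[j]] <- paste0(seqs[[j]], parts[2L])  # interleaved blocks
    }
  }
  if (length(ids) == 0L) stop("no alignment rows in ", path, call. = FALSE)
  rfline <- if (length(rf)) paste(rf, collapse = "") else NULL
  msa(ids, unlist(seqs), rf = rfline)
}

# aligned FASTA: like read_fasta but keeps gap characters
read_fasta_aligned <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L || !grepl("^>", lines[1L])) {
    stop("aligned FASTA parse error in ", path, call. = FALSE)
  }
  idx <- which(grepl("^>", lines))
  bounds <- c(idx, length(lines) + 1L)
  lapply(seq_along(idx), function(j) {
    id <- sub("\\s.*$", "", sub("^>", "", lines[idx[j]]))
    body <- lines[seq.int(idx[j] + 1L, bounds[j + 1L] - 1L, length.out =
                            max(0L, bounds[j + 1L] - idx[j] - 1L))]
    list(id = id, seq = paste(gsub("\\s", "", body), collapse = ""))
  })
}

#' Write an alignment in Stockholm format
#' @param aln An [msa] object.
#' @param path Output path.
#' @export
write_stockholm <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  w <- max(nchar(aln$ids)) + 2L
  for (i in seq_along(aln$ids)) {
    writeLines(sprintf("%-*s%s", w, aln$ids[i], aln$seqs[i]), con)
  }
  if (!is.null(aln$rf)) writeLines(sprintf("%-*s%s", w, "#=GC RF", aln$rf), con)
  writeLines("//", con)
  invisible(NULL)
}

# Integer encoding (1..15 in IUPAC_CODES order) used by the DP kernels.
encode_dna <- function(s) {
  m <- match(strsplit(s, "")[[1]], IUPAC_CODES)
  if (anyNA(m)) stop("cannot encode non-IUPAC residue", call. = FALSE)
  m
}
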