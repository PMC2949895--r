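# Clustal-format alignment output and a minimal reader.

# ClustalX residue classes used for the conservation line.
.strong_groups <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                    "HY", "FYW")
.weak_groups <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SNDEQK",
                  "NDEQHK", "NEQHRK", "FVLIM", "HFY")

#' Construct an alignment object
#'
#' A gapped sequence block: equal-length rows keyed by id.  De-gapping any
#' row must recover the original input sequence.
#'
#' @param ids Character vector of row ids.
#' @param rows Character vector of equal-length gapped strings (`-` gaps;
#'   `.` is normalised to `-`).
#' @param alphabet `"protein"`, `"dna"`, or `"auto"`.
#' @return An object of class `msa_alignment` with fields `ids`, `rows`,
#'   `alphabet` and `L` (column count).
#' @export
msa_alignment <- function(ids, rows, alphabet = "auto") {
  ids <- as.character(ids)
  rows <- gsub(".", "-", toupper(as.character(rows)), fixed = TRUE)
  if (length(ids) != length(rows)) stop("ids and rows must have equal length")
  if (length(ids) < 1L) stop("alignment must be non-empty")
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("alignment rows have unequal lengths")
  if (identical(alphabet, "auto"))
    alphabet <- .guess_alphabet(gsub("-", "", rows, fixed = TRUE))
  structure(list(ids = ids, rows = rows, alphabet = alphabet, L = L),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("msa_alignment: %d rows x %d columns (%s)\n",
              length(x$ids), x$L, x$alphabet))
  invisible(x)
}

# character matrix (rows x columns) view of an alignment
.aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

#' Conservation line of an alignment
#'
#' `*` marks columns where every row carries the same residue and none a
#' gap; for protein alignments `:` and `.` mark columns confined to one of
#' the ClustalX strong or weak residue classes.  Columns containing any gap
#' are never annotated.
#'
#' @param aln An [msa_alignment()].
#' @return A string of length `aln$L`.
#' @export
conservation_line <- function(aln) {
  cm <- .aln_char_matrix(aln)
  strong <- strsplit(.strong_groups, "", fixed = TRUE)
  weak <- strsplit(.weak_groups, "", fixed = TRUE)
  out <- vapply(seq_len(ncol(cm)), function(j) {
    col <- unique(cm[, j])
    if ("-" %in% col) return(" ")
    if (length(col) == 1L) return("*")
    if (aln$alphabet != "protein") return(" ")
    if (any(vapply(strong, function(g) all(col %in% g), logical(1)))) return(":")
    if (any(vapply(weak, function(g) all(col %in% g), logical(1)))) return(".")
    " "
  }, character(1))
  paste(out, collapse = "")
}

#' Write an alignment in Clustal format
#'
#' Blocks of at most 60 columns; the name column is padded to the longest id
#' (truncated at 30 characters) plus three spaces; each block carries the
#' conservation line.
#'
#' @param aln An [msa_alignment()].
#' @param path Output path (conventionally `.aln`).
#' @return `path`, invisibly.
#' @export
write_clustal_aln <- function(aln, path) {
  stopifnot(inherits(aln, "msa_alignment"))
  ids <- substr(aln$ids, 1L, 30L)
  w <- max(nchar(ids)) + 3L
  cons <- conservation_line(aln)
  starts <- seq(1L, aln$L, by = 60L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CLUSTAL multiple sequence alignment", ""), con)
  for (s in starts) {
    e <- min(s + 59L, aln$L)
    for (k in seq_along(aln$ids)) {
      writeLines(sprintf("%-*s%s", w, ids[k], substr(aln$rows[k], s, e)), con)
    }
    writeLines(c(sprintf("%-*s%s", w, "", substr(cons, s, e)), ""), con)
  }
  invisible(path)
}

#' Read a Clustal-format alignment (minimal parser)
#'
#' Parses the block layout written by [write_clustal_aln()]; conservation
#' lines and the header are skipped.
#'
#' @param path Path to a `.aln` file.
#' @param alphabet Passed to [msa_alignment()].
#' @return An [msa_alignment()].
#' @export
read_clustal_aln <- function(path, alphabet = "auto") {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1]))
    stop("'", path, "' does not look like a Clustal alignment")
  lines <- lines[-1]
  rows <- list()
  order <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^[:space:]]+)[[:space:]]+([A-Za-z.\\-]+)[[:space:]]*[0-9]*$", ln))[[1]]
    if (length(m) != 3L) next
    id <- m[2]
    if (!(id %in% order)) order <- c(order, id)
    rows[[id]] <- paste0(if (is.null(rows[[id]])) "" else rows[[id]], m[3])
  }
  if (!length(order)) stop("no alignment rows found in '", path, "'")
  msa_alignment(order, unlist(rows[order], use.names = FALSE), alphabet)
}

#' Export alignment rows as FASTA
#'
#' @param aln An [msa_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  x <- Biostrings::BStringSet(setNames(aln$rows, aln$ids))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}
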