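#' Read a FASTA file into a sequence set
#'
#' Ids are the first whitespace-delimited token after `>`; the remainder of
#' the header line is kept as the description.  Residues are uppercased and
#' line breaks removed.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"`, `"dna"`, or `"auto"` (default) to guess.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path, alphabet = "auto") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  seqs <- gsub("[[:space:]]", "", as.character(set))
  seq_set(ids, seqs, desc, alphabet)
}

#' Write a sequence set to FASTA
#'
#' @param set A [seq_set()].
#' @param path Output path.
#' @param width Residues per line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(set, path, width = 60L) {
  stopifnot(inherits(set, "seq_set"))
  headers <- ifelse(nzchar(set$desc), paste(set$ids, set$desc), set$ids)
  x <- Biostrings::BStringSet(setNames(set$seqs, headers))
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(width))
  invisible(path)
}
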