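#' Residue alphabets
#'
#' The package works with two alphabets: `protein` (the 20 standard amino
#' acids plus `X` for an unknown residue) and `dna` (`ACGT` plus `N`).  Gap
#' characters are `-`; a `.` in input alignments is normalised to `-`.
#'
#' @param alphabet `"protein"` or `"dna"`.
#' @param unknown Include the unknown-residue symbol (`X`/`N`)?
#' @return Character vector of single-letter residue codes.
#' @export
#' @examples
#' alphabet_residues("dna")
alphabet_residues <- function(alphabet = c("protein", "dna"), unknown = TRUE) {
  alphabet <- match.arg(alphabet)
  res <- if (alphabet == "protein") {
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q",
      "R", "S", "T", "V", "W", "Y")
  } else {
    c("A", "C", "G", "T")
  }
  if (unknown) c(res, unknown_symbol(alphabet)) else res
}

unknown_symbol <- function(alphabet) if (alphabet == "protein") "X" else "N"

# First offending position (1-based) of `seq` outside `alphabet`, or 0L.
.first_bad_residue <- function(seq, alphabet) {
  ok <- alphabet_residues(alphabet)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% ok))
  if (length(bad)) bad[1] else 0L
}

# Guess the alphabet of a character vector of sequences.
.guess_alphabet <- function(seqs) {
  ch <- unique(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]])
  if (all(ch %in% c("A", "C", "G", "T", "N"))) "dna" else "protein"
}
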