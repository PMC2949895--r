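#' Construct a sequence set
#'
#' An ordered collection of named, ungapped sequences sharing one alphabet —
#' the unit of an alignment job.
#'
#' @param ids Character vector of unique identifiers (no whitespace).
#' @param seqs Character vector of residue strings (uppercased on input).
#' @param desc Optional free-text descriptions (defaults to empty).
#' @param alphabet `"protein"`, `"dna"`, or `"auto"` to guess from content.
#' @return An object of class `seq_set` with fields `ids`, `seqs`, `desc`,
#'   `alphabet` and `N`.
#' @export
#' @examples
#' s <- seq_set(c("s1", "s2"), c("ACGT", "ACGA"))
#' s$N
seq_set <- function(ids, seqs, desc = NULL, alphabet = "auto") {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length")
  if (length(ids) < 1L) stop("a sequence set needs at least one record")
  if (any(!nzchar(ids)) || any(grepl("[[:space:]]", ids)))
    stop("sequence ids must be non-empty and contain no whitespace")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id: ", dup[1])
  if (any(!nzchar(seqs)))
    stop("empty sequence for id: ", ids[which(!nzchar(seqs))[1]])
  if (identical(alphabet, "auto")) alphabet <- .guess_alphabet(seqs)
  alphabet <- match.arg(alphabet, c("protein", "dna"))
  for (k in seq_along(seqs)) {
    bad <- .first_bad_residue(seqs[k], alphabet)
    if (bad > 0L)
      stop(sprintf("record '%s': residue '%s' at position %d is not in the %s alphabet",
                   ids[k], substr(seqs[k], bad, bad), bad, alphabet))
  }
  if (is.null(desc)) desc <- rep("", length(ids))
  structure(list(ids = ids, seqs = seqs, desc = as.character(desc),
                 alphabet = alphabet, N = length(ids)),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: %d %s sequence(s), lengths %d-%d\n",
              x$N, x$alphabet, min(nchar(x$seqs)), max(nchar(x$seqs))))
  invisible(x)
}

#' @export
length.seq_set <- function(x) x$N

#' Subset a sequence set by index or id
#' @param x A `seq_set`.
#' @param i Integer or character index.
#' @param ... Ignored.
#' @export
`[.seq_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  seq_set(x$ids[i], x$seqs[i], x$desc[i], x$alphabet)
}

#' Search sequences for an exact subsequence
#'
#' Finds every exact occurrence of `query` in each record, the simple
#' partial-sequence finder used to locate motifs in large inputs.
#'
#' @param set A [seq_set()].
#' @param query Non-empty residue string over the set's alphabet.
#' @return A data.frame with columns `id` and `position` (0-based start),
#'   one row per occurrence, in record order; zero rows if absent.
#' @export
#' @examples
#' find_records(seq_set("s1", "ACGTACG"), "ACG")
find_records <- function(set, query) {
  stopifnot(inherits(set, "seq_set"))
  query <- toupper(query)
  if (!nzchar(query)) stop("query must be non-empty")
  bad <- .first_bad_residue(query, set$alphabet)
  if (bad > 0L)
    stop(sprintf("query residue '%s' at position %d is not in the %s alphabet",
                 substr(query, bad, bad), bad, set$alphabet))
  hits <- lapply(seq_len(set$N), function(k) {
    m <- gregexpr(query, set$seqs[k], fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(id = set$ids[k], position = as.integer(m) - 1L,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(id = character(0), position = integer(0),
                       stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  hits
}
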