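# Dual-mode (RAM / disk) symmetric distance-matrix store.
#
# Only the strict upper triangle (i < j) is stored: N(N-1)/2 cells addressed
# by pair_index().  The disk backend is a single fixed-layout binary file:
#
#   bytes 0-7    magic "GMSADM01"
#   bytes 8-11   format version  (int32, little-endian)
#   bytes 12-15  N               (int32)
#   bytes 16-19  cell width in bytes (int32, always 8)
#   body         N(N-1)/2 little-endian doubles, offset = pair_index(i,j,N)
#
# Unwritten cells hold an NaN sentinel (outside [0,1]); reading one is an
# error, which makes incomplete matrices detectable.

.store_magic <- "GMSADM01"
.store_header_bytes <- 20L
.store_cell_bytes <- 8L

#' Canonical index of an unordered sequence pair
#'
#' Row-major enumeration of the strict upper triangle: pair (i, j) with
#' `0 <= i < j < N` maps to `i*(2N-i-1)/2 + (j-i-1)`, a bijection onto
#' `0 .. N(N-1)/2 - 1`.  Computed in double precision (exact below 2^53),
#' since pair counts overflow 32-bit integers for large families.
#'
#' @param i,j 0-based sequence indices, `i < j` (vectorised).
#' @param N Number of sequences.
#' @return Numeric 0-based pair index.
#' @export
#' @examples
#' pair_index(0, 1, 3)  # 0
pair_index <- function(i, j, N) {
  i <- as.numeric(i); j <- as.numeric(j); N <- as.numeric(N)
  if (any(i < 0) || any(i >= j) || any(j >= N))
    stop("pair_index requires 0 <= i < j < N")
  i * (2 * N - i - 1) / 2 + (j - i - 1)
}

#' Number of unordered pairs among N sequences
#'
#' @param N Sequence count.
#' @return `N(N-1)/2` as a double (exact for any realistic N).
#' @export
#' @examples
#' pair_count(52750)
pair_count <- function(N) {
  N <- as.numeric(N)
  N * (N - 1) / 2
}

#' All pairs (i, j) with i < j in canonical order
#'
#' @param N Sequence count.
#' @return Integer matrix with columns `i`, `j` (0-based), rows ordered by
#'   [pair_index()].
#' @export
pair_indices <- function(N) {
  stopifnot(N >= 1)
  if (N < 2) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  i <- rep(0:(N - 2), times = (N - 1):1)
  j <- unlist(lapply(0:(N - 2), function(k) (k + 1):(N - 1)))
  cbind(i = i, j = j)
}

#' Bytes needed by a disk-backed store
#'
#' @param N Sequence count.
#' @return Header plus `8 * N(N-1)/2` bytes, as a double.
#' @export
#' @examples
#' store_required_bytes(400000)
store_required_bytes <- function(N) {
  .store_header_bytes + .store_cell_bytes * pair_count(N)
}

#' Create a distance store
#'
#' @param N Sequence count (>= 2).
#' @param mode `"memory"` (flat triangular vector in RAM) or `"disk"`
#'   (fixed-size binary file, see Details).
#' @param path Disk mode only: file to create (conventionally
#'   `matrix-file080.tmp` inside the job workspace).
#' @return Object of class `dist_store` (an environment with fields `N`,
#'   `mode`, `path`).
#' @export
#' @examples
#' st <- store_create(3, "memory")
#' store_put(st, 0, 1, 0.5)
#' store_get(st, 1, 0)
store_create <- function(N, mode = c("memory", "disk"), path = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(N) || N < 2) stop("a distance store requires N >= 2")
  N <- as.integer(N)
  st <- new.env(parent = emptyenv())
  st$N <- N
  st$mode <- mode
  st$n_written <- 0
  if (mode == "memory") {
    st$cells <- rep(NaN, pair_count(N))
  } else {
    if (is.null(path)) stop("disk mode requires a path")
    if (!dir.exists(dirname(path)) || file.access(dirname(path), 2) != 0)
      stop("spool/store directory not writable: ", dirname(path))
    need <- store_required_bytes(N)
    con <- file(path, "w+b")
    ok <- tryCatch({
      writeChar(.store_magic, con, nchars = 8, eos = NULL)
      writeBin(c(1L, N, .store_cell_bytes), con, size = 4L,
               endian = "little")
      # allocate the full body, sentinel-initialised, in 1 MiB slabs
      slab <- rep(NaN, 131072)
      left <- pair_count(N)
      while (left > 0) {
        k <- min(left, length(slab))
        writeBin(slab[seq_len(k)], con, size = 8L, endian = "little")
        left <- left - k
      }
      flush(con)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      close(con)
      unlink(path)
      stop(sprintf("cannot allocate distance store (%.0f bytes required): %s",
                   need, conditionMessage(ok)))
    }
    st$path <- path
    st$con <- con
  }
  class(st) <- "dist_store"
  st
}

#' Reopen an existing disk-backed store
#'
#' Disk stores survive process restarts: reopening reads the header and
#' gives access to every previously written cell.
#'
#' @param path Path to a store file written by [store_create()].
#' @return A `dist_store`.
#' @export
store_open <- function(path) {
  if (!file.exists(path)) stop("no such store file: ", path)
  con <- file(path, "r+b")
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, .store_magic)) {
    close(con)
    stop("'", path, "' is not a distance store file")
  }
  hdr <- readBin(con, integer(), n = 3L, size = 4L, endian = "little")
  st <- new.env(parent = emptyenv())
  st$N <- hdr[2]
  st$mode <- "disk"
  st$path <- path
  st$con <- con
  st$n_written <- NA_real_
  class(st) <- "dist_store"
  st
}

#' Close a disk-backed store's file handle
#' @param store A `dist_store`.
#' @return `NULL`, invisibly.
#' @export
store_close <- function(store) {
  if (store$mode == "disk" && !is.null(store$con)) {
    close(store$con)
    store$con <- NULL
  }
  invisible(NULL)
}

#' @export
print.dist_store <- function(x, ...) {
  cat(sprintf("dist_store: N = %d, %s mode, %.0f cells\n",
              x$N, x$mode, pair_count(x$N)))
  invisible(x)
}

.store_check_ij <- function(store, i, j) {
  if (i == j) return(NULL)
  lo <- min(i, j); hi <- max(i, j)
  if (lo < 0 || hi >= store$N)
    stop(sprintf("pair (%d, %d) out of range for N = %d", i, j, store$N))
  c(lo, hi)
}

#' Write one distance cell
#'
#' The store is symmetric: `store_put(st, i, j, d)` and
#' `store_put(st, j, i, d)` address the same cell.  Distances must lie in
#' `[0, 1]`; the diagonal is 0 by definition and cannot be written.
#'
#' @param store A `dist_store`.
#' @param i,j 0-based sequence indices, `i != j`.
#' @param d Distance in `[0, 1]`.
#' @return The store, invisibly.
#' @export
store_put <- function(store, i, j, d) {
  ij <- .store_check_ij(store, i, j)
  if (is.null(ij)) stop("cannot write the diagonal: it is 0 by definition")
  if (!is.finite(d) || d < 0 || d > 1)
    stop("distance must lie in [0, 1], got ", d)
  idx <- pair_index(ij[1], ij[2], store$N)
  if (store$mode == "memory") {
    store$cells[idx + 1] <- d
  } else {
    seek(store$con, where = .store_header_bytes + .store_cell_bytes * idx,
         rw = "write")
    writeBin(as.numeric(d), store$con, size = 8L, endian = "little")
  }
  store$n_written <- store$n_written + 1
  invisible(store)
}

#' Read one distance cell
#'
#' @inheritParams store_put
#' @return The stored distance; `0` for `i == j`; an "incomplete matrix"
#'   error for a never-written cell.
#' @export
store_get <- function(store, i, j) {
  ij <- .store_check_ij(store, i, j)
  if (is.null(ij)) return(0)
  idx <- pair_index(ij[1], ij[2], store$N)
  d <- if (store$mode == "memory") {
    store$cells[idx + 1]
  } else {
    seek(store$con, where = .store_header_bytes + .store_cell_bytes * idx,
         rw = "read")
    readBin(store$con, numeric(), n = 1L, size = 8L, endian = "little")
  }
  if (is.nan(d))
    stop(sprintf("incomplete matrix: cell (%d, %d) has not been written",
                 i, j))
  d
}

#' One full row of the distance matrix
#'
#' Streams row `i` (distances to every other sequence) out of the store,
#' the access pattern used by the guide-tree stage in disk mode.
#'
#' @param store A `dist_store`.
#' @param i 0-based row index.
#' @return Numeric vector of length `N` with 0 at position `i + 1`.
#' @export
store_row <- function(store, i) {
  vapply(0:(store$N - 1), function(j) store_get(store, i, j), numeric(1))
}

#' Materialise the full symmetric matrix
#'
#' @param store A complete `dist_store`.
#' @return An `N x N` symmetric numeric matrix with zero diagonal.
#' @export
store_matrix <- function(store) {
  do.call(rbind, lapply(0:(store$N - 1), function(i) store_row(store, i)))
}

#' Has every pair cell been written?
#'
#' @param store A `dist_store`.
#' @return `TRUE` when all `N(N-1)/2` cells hold a non-sentinel value.
#' @export
store_is_complete <- function(store) {
  if (store$mode == "memory") return(!anyNA(store$cells))
  seek(store$con, where = .store_header_bytes, rw = "read")
  left <- pair_count(store$N)
  while (left > 0) {
    k <- min(left, 131072)
    v <- readBin(store$con, numeric(), n = k, size = 8L, endian = "little")
    if (anyNA(v)) return(FALSE)
    left <- left - k
  }
  TRUE
}

#' Spool per-pair FASTA files
#'
#' Writes one two-record FASTA file per sequence pair in canonical order,
#' named `<stem>-%09d.fa` where the nine-digit suffix is the pair index P —
#' the on-disk work-unit layout consumed by distance-phase workers.  The
#' `first`/`last` window allows streamed generation of a slice of the spool
#' so it never needs to exist in full at once.
#'
#' @param seqset A [seq_set()].
#' @param dir Spool directory (created if needed).
#' @param stem File-name stem (default `"pair"`).
#' @param first,last Optional 0-based pair-index window (inclusive).
#' @return Character vector of the file paths written, invisibly.
#' @export
spool_pairs <- function(seqset, dir, stem = "pair", first = 0,
                        last = pair_count(seqset$N) - 1) {
  stopifnot(inherits(seqset, "seq_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("spool directory not writable: ", dir)
  if (seqset$N < 2) return(invisible(character(0)))
  ij <- pair_indices(seqset$N)
  total <- nrow(ij)
  first <- max(0, first); last <- min(total - 1, last)
  if (first > last) return(invisible(character(0)))
  paths <- character(0)
  for (p in first:last) {
    i <- ij[p + 1, 1]; j <- ij[p + 1, 2]
    path <- file.path(dir, sprintf("%s-%09d.fa", stem, p))
    write_fasta(seqset[c(i, j) + 1L], path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
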