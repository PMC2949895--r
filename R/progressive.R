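# Stage (3): weighted profile-profile progressive alignment, SP scoring,
# and window realignment.
#
# A profile is a gapped block summarised, column by column, by weighted
# residue frequencies (gap mass excluded).  Merging two profiles is an
# affine-gap DP over the column-pair score
#   m(c1, c2) = sum_a sum_b f1(a, c1) f2(b, c2) s(a, b),
# with the same deterministic tie-breaks as the pairwise aligner.  Gaps
# introduced by earlier merges are never removed ("once a gap, always a
# gap"): a merge only inserts whole gap columns into existing rows.

# weighted residue frequency matrix (residues x columns), gap mass excluded
.profile_freq <- function(cm, weights, residues) {
  f <- matrix(0, length(residues), ncol(cm),
              dimnames = list(residues, NULL))
  for (r in seq_along(residues))
    f[r, ] <- colSums((cm == residues[r]) * weights)
  f / sum(weights)
}

# merge two profiles (lists: ids, cm (char matrix), weights) under params
.merge_profiles <- function(p1, p2, params) {
  S <- params$matrix$scores
  residues <- rownames(S)
  f1 <- .profile_freq(p1$cm, p1$weights, residues)
  f2 <- .profile_freq(p2$cm, p2$weights, residues)
  M <- crossprod(f1, S %*% f2)          # L1 x L2 column-pair scores
  r <- gotoh_align(M, params$gap_open, params$gap_extend)
  moves <- r$moves
  L <- length(moves)
  sel1 <- moves != 3L
  sel2 <- moves != 2L
  pos1 <- cumsum(sel1)
  pos2 <- cumsum(sel2)
  cm1 <- matrix("-", nrow(p1$cm), L)
  cm2 <- matrix("-", nrow(p2$cm), L)
  cm1[, sel1] <- p1$cm[, pos1[sel1]]
  cm2[, sel2] <- p2$cm[, pos2[sel2]]
  list(ids = c(p1$ids, p2$ids), cm = rbind(cm1, cm2),
       weights = c(p1$weights, p2$weights))
}

#' Progressive multiple alignment along a guide tree
#'
#' Aligns the sequences by successive profile-profile merges in the tree's
#' join order.  Row order of the result follows the input order of
#' `seqset`; de-gapping any output row recovers its input sequence exactly.
#'
#' @param seqset A [seq_set()].
#' @param tree A [nj_tree()] guide tree over the same ids (ignored for
#'   `N = 1`).
#' @param weights Named sequence weights from [sequence_weights()];
#'   defaults to computing them from `tree`.
#' @param params An [align_params()].
#' @return An [msa_alignment()].
#' @export
progressive_align <- function(seqset, tree, weights = NULL,
                              params = align_params()) {
  stopifnot(inherits(seqset, "seq_set"))
  if (seqset$N == 1L)
    return(msa_alignment(seqset$ids, seqset$seqs, seqset$alphabet))
  stopifnot(inherits(tree, "guide_tree"))
  if (!setequal(tree$ids, seqset$ids))
    stop("guide-tree leaves do not match the sequence set")
  if (is.null(weights)) weights <- sequence_weights(tree)
  weights <- weights[tree$ids]
  if (anyNA(weights)) stop("weights must be named by sequence id")
  nt <- length(tree$ids)
  profiles <- vector("list", nt + nrow(tree$join_order))
  for (k in seq_len(nt)) {
    seq <- seqset$seqs[match(tree$ids[k], seqset$ids)]
    profiles[[k]] <- list(ids = tree$ids[k],
                          cm = matrix(strsplit(seq, "", fixed = TRUE)[[1]],
                                      nrow = 1),
                          weights = unname(weights[k]))
  }
  for (k in seq_len(nrow(tree$join_order))) {
    j <- tree$join_order[k, ]
    profiles[[j$node]] <- .merge_profiles(profiles[[j$child1]],
                                          profiles[[j$child2]], params)
    profiles[j$child1] <- list(NULL)    # free merged children
    profiles[j$child2] <- list(NULL)
  }
  root <- profiles[[tree$join_order$node[nrow(tree$join_order)]]]
  ord <- match(seqset$ids, root$ids)
  rows <- apply(root$cm[ord, , drop = FALSE], 1, paste, collapse = "")
  msa_alignment(seqset$ids, rows, seqset$alphabet)
}

#' Sum-of-pairs score of an alignment
#'
#' Total over all unordered row pairs of the affine-gap score of the two
#' gapped rows: substitution scores on residue-residue columns, gap runs
#' against a residue cost `gap_open + len * gap_extend`, and columns where
#' both rows are gaps are ignored.  The weighted variant multiplies each
#' pair term by `w_i * w_j`; with all weights 1 it equals the unweighted
#' score.
#'
#' @param aln An [msa_alignment()].
#' @param params An [align_params()].
#' @param weights Optional named weight vector (default all 1).
#' @return A single numeric score.
#' @export
sp_score <- function(aln, params = align_params(), weights = NULL) {
  stopifnot(inherits(aln, "msa_alignment"))
  S <- params$matrix$scores
  cm <- .aln_char_matrix(aln)
  enc <- match(cm, rownames(S))
  enc[cm == "-"] <- 0L
  if (anyNA(enc)) stop("alignment contains residues not covered by matrix")
  enc <- matrix(enc, nrow = nrow(cm))
  w <- if (is.null(weights)) rep(1, nrow(cm)) else unname(weights[aln$ids])
  if (anyNA(w)) stop("weights must be named by row id")
  sp_score_encoded(enc, S, params$gap_open, params$gap_extend, w)
}

#' Realign a column window of an alignment
#'
#' Extracts the rows of the half-open column window `[col_start, col_end)`,
#' strips their gaps, re-runs the full three-stage pipeline (distances,
#' guide tree, progressive alignment) on the fragments, and splices the
#' result back.  Columns outside the window are untouched byte for byte; a
#' row whose fragment is empty re-enters the new window as all gaps.
#'
#' @param aln An [msa_alignment()].
#' @param col_start,col_end 0-based half-open column window,
#'   `0 <= col_start < col_end <= L`.
#' @param params An [align_params()].
#' @return An [msa_alignment()]; the window width may change.
#' @export
realign_region <- function(aln, col_start, col_end,
                           params = align_params()) {
  stopifnot(inherits(aln, "msa_alignment"))
  if (!(col_start >= 0 && col_start < col_end && col_end <= aln$L))
    stop("need 0 <= col_start < col_end <= ", aln$L)
  left <- substr(aln$rows, 1L, col_start)
  mid <- substr(aln$rows, col_start + 1L, col_end)
  right <- substr(aln$rows, col_end + 1L, aln$L)
  frags <- gsub("-", "", mid, fixed = TRUE)
  keep <- nzchar(frags)
  new_mid <- if (!any(keep)) {
    rep("", length(frags))
  } else if (sum(keep) == 1L) {
    out <- rep(strrep("-", nchar(frags[keep])), length(frags))
    out[keep] <- frags[keep]
    out
  } else {
    sub <- seq_set(aln$ids[keep], frags[keep], alphabet = aln$alphabet)
    res <- align_sequences(sub, params = params)
    out <- rep(strrep("-", res$alignment$L), length(frags))
    out[keep] <- res$alignment$rows[match(aln$ids[keep],
                                          res$alignment$ids)]
    out
  }
  msa_alignment(aln$ids, paste0(left, new_mid, right), aln$alphabet)
}

#' Run the three-stage alignment pipeline in memory
#'
#' Convenience core used by [cmd_align()] and [realign_region()]:
#' all-pair distances, neighbor-joining guide tree, branch-sharing weights,
#' progressive alignment.
#'
#' @param seqset A [seq_set()].
#' @param params An [align_params()].
#' @param store Optional pre-created [store_create()] result (defaults to a
#'   memory store).
#' @param config A [scheduler_config()].
#' @param executor Passed to [run_distance_phase()].
#' @param checkpoint_dir Passed to [nj_tree()].
#' @param progress Passed to [run_distance_phase()].
#' @return List with `alignment`, `tree`, `weights`, `store`.
#' @export
align_sequences <- function(seqset, params = align_params(), store = NULL,
                            config = scheduler_config(),
                            executor = "serial", checkpoint_dir = NULL,
                            progress = NULL) {
  stopifnot(inherits(seqset, "seq_set"))
  if (seqset$N == 1L)
    return(list(alignment = msa_alignment(seqset$ids, seqset$seqs,
                                          seqset$alphabet),
                tree = NULL, weights = setNames(1, seqset$ids),
                store = NULL))
  if (is.null(store)) store <- store_create(seqset$N, "memory")
  run_distance_phase(seqset, params, store, config, executor, progress)
  tree <- nj_tree(store, seqset$ids, checkpoint_dir)
  weights <- sequence_weights(tree)
  aln <- progressive_align(seqset, tree, weights, params)
  list(alignment = aln, tree = tree, weights = weights, store = store)
}
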