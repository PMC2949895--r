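# Stage (2): neighbor-joining guide tree, sequence weights, checkpoints.

#' Neighbor-joining guide tree from a distance store
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion.  Ties on Q are
#' broken deterministically towards the lexicographically lowest cluster
#' pair (clusters keep their creation order).  A negative branch length is
#' clamped to zero and its deficit moved to the sibling branch, preserving
#' the pair's total.  The final unrooted tree is midpoint-rooted (the root
#' bisects the longest leaf-to-leaf path), giving the rooted binary tree
#' that drives progressive alignment; for `N = 2` the single join is split
#' into equal halves.
#'
#' @param store A complete [store_create()] result (`N >= 2`).
#' @param ids Leaf labels in sequence order (default `s1..sN`).
#' @param checkpoint_dir Optional directory: after construction the join
#'   history is replayed into stage-numbered Newick snapshots via
#'   [checkpoint_tree()].
#' @return Object of class `guide_tree`: fields `phylo` (rooted binary
#'   `ape` tree), `ids`, and `join_order` (data.frame `node`, `child1`,
#'   `child2` in dependency order; tips are nodes `1..N`).
#' @export
nj_tree <- function(store, ids = NULL, checkpoint_dir = NULL) {
  stopifnot(inherits(store, "dist_store"))
  N <- store$N
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(N))
  if (length(ids) != N) stop("need one id per sequence")
  D <- store_matrix(store)  # errors if any cell is unwritten
  phy <- .nj_phylo(D, ids)
  tree <- .as_guide_tree(phy, ids)
  if (!is.null(checkpoint_dir)) checkpoint_tree(tree, checkpoint_dir)
  tree
}

# Core NJ on a dense matrix; returns a rooted binary ape tree.
.nj_phylo <- function(D, ids) {
  N <- nrow(D)
  lab <- .newick_label(ids)
  if (N == 2) {
    b <- .newick_num(D[1, 2] / 2)
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                         lab[1], b, lab[2], b)))
  }
  frag <- lab                 # newick fragment per active cluster
  act <- seq_len(N)           # creation order is the tie-break order
  while (length(act) > 3) {
    n <- length(act)
    Dm <- D[act, act, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    a <- hit[1, 1]; b <- hit[1, 2]
    d_ab <- Dm[a, b]
    ba <- d_ab / 2 + (r[a] - r[b]) / (2 * (n - 2))
    bb <- d_ab - ba
    if (ba < 0) { bb <- bb - ba; ba <- 0 }
    if (bb < 0) { ba <- ba - bb; bb <- 0 }
    ia <- act[a]; ib <- act[b]
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[ia], .newick_num(ba),
                        frag[ib], .newick_num(bb))
    # distances from the new cluster to the others
    others <- act[-c(a, b)]
    dnew <- (D[ia, others] + D[ib, others] - d_ab) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, others] <- dnew
    D[others, u] <- dnew
    frag <- c(frag, new_frag)
    # keep creation order: the new cluster takes the place of the earlier
    # member of the merged pair
    act <- append(act[-c(a, b)], u, after = a - 1)
  }
  i <- act[1]; j <- act[2]; k <- act[3]
  b1 <- max(0, (D[i, j] + D[i, k] - D[j, k]) / 2)
  b2 <- max(0, (D[i, j] + D[j, k] - D[i, k]) / 2)
  b3 <- max(0, (D[i, k] + D[j, k] - D[i, j]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[i], .newick_num(b1),
                 frag[j], .newick_num(b2), frag[k], .newick_num(b3))
  unrooted <- ape::read.tree(text = txt)
  rooted <- phangorn::midpoint(unrooted)
  if (!ape::is.binary.phylo(rooted)) rooted <- ape::multi2di(rooted)
  rooted$edge.length[is.na(rooted$edge.length)] <- 0
  rooted$edge.length[rooted$edge.length < 0] <- 0
  rooted
}

# wrap a rooted binary phylo as a guide_tree: tips renumbered to input
# order, join_order in postorder (children before parents)
.as_guide_tree <- function(phy, ids) {
  ord <- match(ids, phy$tip.label)
  if (anyNA(ord)) stop("tree labels do not match sequence ids")
  # renumber tips so tip k corresponds to ids[k]
  map <- integer(length(ids))
  map[ord] <- seq_along(ids)
  phy$edge[phy$edge[, 2] <= length(ids), 2] <-
    map[phy$edge[phy$edge[, 2] <= length(ids), 2]]
  phy$tip.label <- ids
  po <- ape::reorder.phylo(phy, "postorder")
  internal <- unique(po$edge[, 1])  # parents in postorder completion order
  join <- do.call(rbind, lapply(internal, function(nd) {
    ch <- po$edge[po$edge[, 1] == nd, 2]
    data.frame(node = nd, child1 = ch[1], child2 = ch[2])
  }))
  structure(list(phylo = po, ids = ids, join_order = join),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("guide_tree: %d leaves, %d joins\n",
              length(x$ids), nrow(x$join_order)))
  invisible(x)
}

# newick fragment (with branch lengths) for every node of the rooted tree
.node_fragments <- function(tree) {
  phy <- tree$phylo
  nt <- length(phy$tip.label)
  frag <- character(nt + phy$Nnode)
  frag[seq_len(nt)] <- .newick_label(phy$tip.label)
  elen <- setNames(phy$edge.length, phy$edge[, 2])
  for (k in seq_len(nrow(tree$join_order))) {
    j <- tree$join_order[k, ]
    frag[j$node] <- sprintf("(%s:%s,%s:%s)",
                            frag[j$child1], .newick_num(elen[[as.character(j$child1)]]),
                            frag[j$child2], .newick_num(elen[[as.character(j$child2)]]))
  }
  frag
}

#' Write per-join tree checkpoints
#'
#' Replays the tree's join history, writing after each of the `N - 1` joins
#' a stage-numbered Newick snapshot (`<stem>-%09d.nwk`, the same nine-digit
#' suffix convention as the pair spool).  Each snapshot holds one Newick
#' line per cluster still active at that stage; the final snapshot is the
#' complete guide tree.
#'
#' @param tree A [nj_tree()] result.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem (default `"tree"`).
#' @return Character vector of snapshot paths, invisibly.
#' @export
checkpoint_tree <- function(tree, dir, stem = "tree") {
  stopifnot(inherits(tree, "guide_tree"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("checkpoint directory not writable: ", dir)
  frag <- .node_fragments(tree)
  active <- as.list(seq_along(tree$ids))
  paths <- character(0)
  for (k in seq_len(nrow(tree$join_order))) {
    j <- tree$join_order[k, ]
    active <- active[!(unlist(active) %in% c(j$child1, j$child2))]
    active <- c(active, j$node)
    path <- file.path(dir, sprintf("%s-%09d.nwk", stem, k))
    writeLines(paste0(frag[unlist(active)], ";"), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Progressive-alignment sequence weights
#'
#' Branch-sharing weights: each leaf's weight is the sum, over the branches
#' on its path to the root, of branch length divided by the number of
#' leaves sharing that branch.  Weights are normalised to a maximum of 1;
#' if every branch length is zero the weights are uniform.
#'
#' @param tree A [nj_tree()] result.
#' @return Named numeric vector (names = sequence ids), all > 0, max = 1.
#' @export
sequence_weights <- function(tree) {
  stopifnot(inherits(tree, "guide_tree"))
  phy <- tree$phylo
  nt <- length(phy$tip.label)
  w <- numeric(nt)
  below <- phangorn::Descendants(phy, seq_len(nt + phy$Nnode), "tips")
  for (k in seq_len(nrow(phy$edge))) {
    child <- phy$edge[k, 2]
    tips <- below[[child]]
    w[tips] <- w[tips] + phy$edge.length[k] / length(tips)
  }
  if (all(w == 0)) w <- rep(1, nt)
  w <- w / max(w)
  setNames(w, phy$tip.label)
}
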