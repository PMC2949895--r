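# Newick serialization of guide trees.

# Quote a label if it contains Newick metacharacters or whitespace;
# embedded single quotes are doubled, per the Newick convention.
.newick_label <- function(x) {
  needs <- grepl("[][(),:;'[:space:]]", x)
  ifelse(needs, paste0("'", gsub("'", "''", x, fixed = TRUE), "'"), x)
}

.newick_num <- function(x) sprintf("%.10g", x)

# Serialize an ape "phylo" object (with edge lengths) to a Newick string.
.phylo_to_newick <- function(tree) {
  nt <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    if (node <= nt) return(.newick_label(tree$tip.label[node]))
    e <- kids[[as.character(node)]]
    parts <- vapply(e, function(k) {
      paste0(rec(tree$edge[k, 2]), ":", .newick_num(tree$edge.length[k]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(nt + 1L), ";")
}

#' Write a tree in Newick format
#'
#' @param tree A [guide_tree] (from [nj_tree()]) or an `ape` `phylo` object.
#' @param path Output path (conventionally `.dnd`).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "guide_tree")) tree$phylo else tree
  if (!inherits(phy, "phylo")) stop("tree must be a guide_tree or phylo object")
  writeLines(.phylo_to_newick(phy), path)
  invisible(path)
}

#' Read a Newick tree file
#'
#' Thin wrapper over [ape::read.tree()], used to round-trip guide trees.
#'
#' @param path Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("cannot parse Newick file: ", path)
  tr
}
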