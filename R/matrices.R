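# Substitution-matrix catalogue.
#
# Two sources feed the catalogue:
#   * the ten classic log-odds tables bundled with Biostrings
#     (BLOSUM45/50/62/80/100, PAM30/40/70/120/250), and
#   * half-bit log-odds matrices computed from the empirical amino-acid
#     replacement models shipped with phangorn (Dayhoff, JTT, WAG, LG, VT,
#     ...) evaluated at a chosen evolutionary distance in PAM units
#     (1 PAM = 1% expected substitutions per site).  PAM160/PAM350/PAM500
#     are the Dayhoff chain itself at those distances.
# A simple identity/mismatch table serves nucleic acids.

.aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")

.biostrings_matrices <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
                          "BLOSUM100", "PAM30", "PAM40", "PAM70", "PAM120",
                          "PAM250")

.model_distances <- c(100L, 250L)

.phangorn_models <- function() {
  getFromNamespace(".aamodels", "phangorn")
}

# every model-derived catalogue entry: name, source model, PAM distance
.model_combos <- function() {
  models <- .phangorn_models()
  grid <- expand.grid(model = models, pam = .model_distances,
                      stringsAsFactors = FALSE)
  grid$name <- paste0(toupper(grid$model), grid$pam)
  extra <- data.frame(model = "Dayhoff", pam = c(160, 350, 500),
                      name = c("PAM160", "PAM350", "PAM500"),
                      stringsAsFactors = FALSE)
  rbind(grid, extra)
}

#' Validate and wrap a substitution matrix
#'
#' @param name Matrix name.
#' @param alphabet `"protein"` or `"dna"`.
#' @param scores Square numeric matrix with identical row/column names
#'   covering the full alphabet (including the unknown symbol).
#' @return Object of class `subst_matrix` (fields `name`, `alphabet`,
#'   `scores`).
#' @export
subst_matrix <- function(name, alphabet, scores) {
  alphabet <- match.arg(alphabet, c("protein", "dna"))
  res <- alphabet_residues(alphabet)
  if (!is.matrix(scores) || is.null(rownames(scores)) ||
      !identical(rownames(scores), colnames(scores)))
    stop("scores must be a square matrix with matching dimnames")
  missing <- setdiff(res, rownames(scores))
  if (length(missing))
    stop("matrix '", name, "' lacks residues: ", paste(missing, collapse = ","))
  scores <- scores[res, res, drop = FALSE]
  if (max(abs(scores - t(scores))) > 1e-9)
    stop("matrix '", name, "' is not symmetric")
  structure(list(name = name, alphabet = alphabet, scores = scores),
            class = "subst_matrix")
}

#' @export
print.subst_matrix <- function(x, ...) {
  cat(sprintf("subst_matrix '%s' (%s), %d residues, score range [%g, %g]\n",
              x$name, x$alphabet, nrow(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

# Ensure the unknown symbol has a row/column; absent entries get the matrix
# minimum, so unknown residues never outscore an informative pairing.
.with_unknown <- function(scores, alphabet) {
  u <- unknown_symbol(alphabet)
  if (!(u %in% rownames(scores))) {
    lo <- min(scores)
    scores <- rbind(cbind(scores, lo), lo)
    rownames(scores)[nrow(scores)] <- u
    colnames(scores)[ncol(scores)] <- u
  }
  scores
}

# Half-bit log-odds matrix from a reversible replacement model at `pam`
# PAM units: s(a,b) = round(2 * log2(P(b | a, t) / pi_b)).
.model_logodds <- function(model, pam) {
  tmp <- get(paste0(".", model), environment(phangorn::pml))
  bf <- as.numeric(tmp$bf)
  ex <- matrix(0, 20, 20)
  ex[lower.tri(ex)] <- tmp$Q
  ex <- ex + t(ex)
  R <- ex %*% diag(bf)
  diag(R) <- -rowSums(R)
  rate <- -sum(bf * diag(R))
  R <- R * (0.01 / rate)                       # 1 PAM per unit t
  # reversible: symmetrize via pi^1/2 R pi^-1/2, then eigendecompose
  s <- sqrt(bf)
  B <- diag(s) %*% R %*% diag(1 / s)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  P <- diag(1 / s) %*% eig$vectors %*% diag(exp(eig$values * pam)) %*%
    t(eig$vectors) %*% diag(s)
  odds <- P %*% diag(1 / bf)
  odds <- (odds + t(odds)) / 2                 # exact symmetry
  sc <- round(2 * log2(pmax(odds, 1e-12)))
  dimnames(sc) <- list(.aa20, .aa20)
  sc
}

.dna_scores <- function() {
  res <- c("A", "C", "G", "T")
  sc <- matrix(0, 4, 4, dimnames = list(res, res))
  diag(sc) <- 1.9                              # Clustal-style DNA match score
  n <- rbind(cbind(sc, 0), 0)
  rownames(n)[5] <- colnames(n)[5] <- "N"
  n
}

#' List the bundled weight matrices
#'
#' @return A data.frame with columns `name`, `alphabet` and `source`
#'   (`biostrings`, `model` or `builtin`), one row per matrix.
#' @export
#' @examples
#' nrow(subset(list_weight_matrices(), alphabet == "protein")) >= 34
list_weight_matrices <- function() {
  combo <- .model_combos()
  data.frame(
    name = c(.biostrings_matrices, combo$name, "DNA"),
    alphabet = c(rep("protein", length(.biostrings_matrices) + nrow(combo)),
                 "dna"),
    source = c(rep("biostrings", length(.biostrings_matrices)),
               rep("model", nrow(combo)), "builtin"),
    stringsAsFactors = FALSE)
}

#' Load a weight matrix by name
#'
#' Looks the name up in the catalogue ([list_weight_matrices()]), builds the
#' score table, attaches a score row/column for the unknown residue (matrix
#' minimum when the source table lacks one) and validates symmetry and
#' completeness.
#'
#' @param name Catalogue name, e.g. `"BLOSUM62"`, `"PAM350"`, `"DAYHOFF250"`.
#' @return A [subst_matrix()].
#' @export
#' @examples
#' m <- load_weight_matrix("BLOSUM62")
#' m$scores["A", "A"]
load_weight_matrix <- function(name) {
  name <- toupper(name)
  key <- paste0("matrix:", name)
  if (!is.null(.gridmsa_cache[[key]])) return(.gridmsa_cache[[key]])
  cat_df <- list_weight_matrices()
  if (!(name %in% cat_df$name))
    stop("unknown weight matrix '", name, "'; available: ",
         paste(cat_df$name, collapse = ", "))
  row <- cat_df[cat_df$name == name, ]
  scores <- if (row$source == "biostrings") {
    e <- new.env()
    data(list = name, package = "Biostrings", envir = e)
    sc <- get(name, envir = e)
    keep <- intersect(c(.aa20, "X"), rownames(sc))
    sc[keep, keep, drop = FALSE] * 1.0
  } else if (row$source == "model") {
    combo <- .model_combos()
    k <- match(name, combo$name)
    .model_logodds(combo$model[k], combo$pam[k])
  } else {
    .dna_scores()
  }
  scores <- .with_unknown(scores, row$alphabet)
  out <- subst_matrix(name, row$alphabet, scores)
  .gridmsa_cache[[key]] <- out
  out
}
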