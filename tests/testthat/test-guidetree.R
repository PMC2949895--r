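test_that("two leaves join at half the distance", {
  st <- store_from_matrix(matrix(c(0, 0.4, 0.4, 0), 2))
  tr <- nj_tree(st, c("a", "b"))
  expect_equal(sort(tr$phylo$tip.label), c("a", "b"))
  expect_equal(unname(tr$phylo$edge.length), c(0.2, 0.2))
})

test_that("an additive 4-taxon matrix is inverted exactly", {
  # tree ((a:0.10, b:0.20):0.05, (c:0.15, d:0.30):0.05) -> path lengths
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 0.30
  D["a", "c"] <- D["c", "a"] <- 0.35
  D["a", "d"] <- D["d", "a"] <- 0.50
  D["b", "c"] <- D["c", "b"] <- 0.45
  D["b", "d"] <- D["d", "b"] <- 0.60
  D["c", "d"] <- D["d", "c"] <- 0.45
  st <- store_from_matrix(D)
  tr <- nj_tree(st, letters[1:4])
  co <- ape::cophenetic.phylo(tr$phylo)[letters[1:4], letters[1:4]]
  expect_equal(co, D, tolerance = 1e-9)
  # ab | cd split present
  gen <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.05);")
  expect_equal(ape::dist.topo(ape::unroot(tr$phylo), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
})

test_that("random additive matrices recover their generating topology", {
  withr::local_seed(99)
  for (rep in 1:20) {
    gen <- ape::rtree(8)
    gen$edge.length <- runif(nrow(gen$edge), 0.05, 1.0)
    D <- ape::cophenetic.phylo(gen)
    D <- D / max(D)   # distances live in [0, 1]
    st <- store_from_matrix(D[order(rownames(D)), order(colnames(D))])
    tr <- nj_tree(st, sort(rownames(D)))
    expect_equal(ape::dist.topo(ape::unroot(tr$phylo), ape::unroot(gen)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("tree shape is invariant to input order", {
  withr::local_seed(13)
  N <- 7
  D <- matrix(0, N, N)
  D[upper.tri(D)] <- runif(N * (N - 1) / 2, 0.1, 0.9)
  D <- D + t(D)
  ids <- sprintf("s%d", 1:N)
  dimnames(D) <- list(ids, ids)
  t1 <- nj_tree(store_from_matrix(D), ids)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  t2 <- nj_tree(store_from_matrix(D[perm, perm]), ids[perm])
  expect_equal(ape::dist.topo(ape::unroot(t1$phylo), ape::unroot(t2$phylo)),
               0, ignore_attr = TRUE)
})

test_that("internal nodes partition their leaves", {
  set <- random_seq_set(9, alphabet = "protein", seed = 17)
  res <- align_sequences(set, align_params("BLOSUM62"))
  tr <- res$tree
  below <- phangorn::Descendants(tr$phylo,
                                 seq_len(set$N + tr$phylo$Nnode), "tips")
  for (k in seq_len(nrow(tr$join_order))) {
    j <- tr$join_order[k, ]
    expect_setequal(below[[j$node]],
                    c(below[[j$child1]], below[[j$child2]]))
    expect_length(intersect(below[[j$child1]], below[[j$child2]]), 0)
  }
})

test_that("branch-sharing weights match hand-computed path sums", {
  # caterpillar ((a:0.1, b:0.1):0.2, c:0.4) rooted with branch r:0.0 above
  phy <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,c:0.4);")
  gt <- gridmsa:::.as_guide_tree(phy, c("a", "b", "c"))
  w <- sequence_weights(gt)
  raw <- c(a = 0.1 + 0.2 / 2, b = 0.1 + 0.2 / 2, c = 0.4)
  expect_equal(w, raw / max(raw))

  # zero branch lengths -> uniform weights of 1
  phy0 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  gt0 <- gridmsa:::.as_guide_tree(phy0, c("a", "b", "c"))
  expect_equal(unname(sequence_weights(gt0)), c(1, 1, 1))

  # balanced tree with equal branch lengths -> equal weights of 1
  phyb <- ape::read.tree(text = "((a:0.2,b:0.2):0.2,(c:0.2,d:0.2):0.2);")
  gtb <- gridmsa:::.as_guide_tree(phyb, letters[1:4])
  expect_equal(unname(sequence_weights(gtb)), rep(1, 4))
})

test_that("checkpointing writes one forest snapshot per join", {
  D <- matrix(c(0, .2, .5, .6,
                .2, 0, .5, .6,
                .5, .5, 0, .3,
                .6, .6, .3, 0), 4)
  st <- store_from_matrix(D)
  dir <- withr::local_tempdir()
  tr <- nj_tree(st, letters[1:4], checkpoint_dir = dir)
  files <- list.files(dir)
  expect_identical(files, sprintf("tree-%09d.nwk", 1:3))
  last <- ape::read.tree(file.path(dir, files[3]))
  expect_equal(ape::dist.topo(ape::unroot(last), ape::unroot(tr$phylo)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(last)[letters[1:4], letters[1:4]],
               ape::cophenetic.phylo(tr$phylo)[letters[1:4], letters[1:4]],
               tolerance = 1e-9)
  # earlier snapshots hold shrinking forests
  expect_length(readLines(file.path(dir, files[1])), 3)
  expect_length(readLines(file.path(dir, files[2])), 2)
  expect_length(readLines(file.path(dir, files[3])), 1)
})
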