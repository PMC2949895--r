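test_that("two sequences align identically to the pairwise aligner", {
  p <- align_params("BLOSUM62")
  set <- random_seq_set(2, c(15, 25), alphabet = "protein", seed = 41)
  res <- align_sequences(set, p)
  pw <- nw_align(set$seqs[1], set$seqs[2], p)
  expect_identical(res$alignment$rows, c(pw$row_a, pw$row_b))
})

test_that("identical sequences produce a gap-free block", {
  set <- seq_set(sprintf("s%d", 1:5), rep("MKVLAWQH", 5))
  res <- align_sequences(set, align_params("BLOSUM62"))
  expect_equal(res$alignment$L, 8)
  expect_true(all(res$alignment$rows == "MKVLAWQH"))
})

test_that("de-gapping any progressive alignment recovers the inputs", {
  for (seed in c(2, 8, 15)) {
    set <- random_seq_set(7, c(5, 40),
                          alphabet = if (seed == 8) "protein" else "dna",
                          seed = seed)
    p <- if (seed == 8) align_params("BLOSUM62") else align_params("DNA")
    res <- align_sequences(set, p)
    expect_identical(res$alignment$ids, set$ids)  # row order follows input
    expect_identical(gsub("-", "", res$alignment$rows), set$seqs)
    expect_gte(res$alignment$L, max(nchar(set$seqs)))
  }
})

test_that("SP score equals per-pair recounts and closed forms", {
  p <- align_params("BLOSUM62", 10, 0.5)
  # 2-row alignment scores as the pair itself
  set <- random_seq_set(2, c(10, 20), alphabet = "protein", seed = 55)
  pw <- nw_align(set$seqs[1], set$seqs[2], p)
  a2 <- msa_alignment(set$ids, c(pw$row_a, pw$row_b), "protein")
  expect_equal(sp_score(a2, p), pw$score)

  # k identical rows "AC": C(k,2) * (s(A,A) + s(C,C))
  for (k in c(3, 6)) {
    ak <- msa_alignment(sprintf("r%d", 1:k), rep("AC", k), "protein")
    expect_equal(sp_score(ak, p),
                 choose(k, 2) * (p$matrix$scores["A", "A"] +
                                   p$matrix$scores["C", "C"]),
                 ignore_attr = TRUE)
  }

  # naive double-loop recount on a real alignment with gaps
  set <- random_seq_set(6, c(8, 25), alphabet = "protein", seed = 77)
  res <- align_sequences(set, p)
  aln <- res$alignment
  naive <- 0
  for (i in 1:5) for (j in (i + 1):6)
    naive <- naive + score_gapped_pair(aln$rows[i], aln$rows[j], p)
  expect_equal(sp_score(aln, p), naive, ignore_attr = TRUE)

  # unit weights equal the unweighted score; weights scale pair terms
  w1 <- setNames(rep(1, 6), aln$ids)
  expect_equal(sp_score(aln, p, w1), sp_score(aln, p))
  wh <- setNames(rep(0.5, 6), aln$ids)
  expect_equal(sp_score(aln, p, wh), 0.25 * sp_score(aln, p))
})

test_that("window realignment keeps outside columns byte-identical", {
  withr::local_seed(3)
  set <- random_seq_set(6, c(20, 35), alphabet = "protein", seed = 91)
  p <- align_params("BLOSUM62")
  res <- align_sequences(set, p)
  aln <- res$alignment
  for (win in list(c(0, aln$L), c(4, 12), c(0, 5), c(aln$L - 6, aln$L))) {
    ra <- realign_region(aln, win[1], win[2], p)
    expect_identical(substr(ra$rows, 1, win[1]),
                     substr(aln$rows, 1, win[1]))
    tail_new <- substr(ra$rows, ra$L - (aln$L - win[2]) + 1, ra$L)
    tail_old <- substr(aln$rows, win[2] + 1, aln$L)
    expect_identical(tail_new, tail_old)
    expect_identical(gsub("-", "", ra$rows), set$seqs)
  }
  # whole-window realignment equals a fresh pipeline on the inputs
  whole <- realign_region(aln, 0, aln$L, p)
  fresh <- align_sequences(set, p)
  expect_identical(whole$rows, fresh$alignment$rows)
})

test_that("an all-gap window shrinks away without touching the rest", {
  aln <- msa_alignment(c("a", "b"), c("AC--GT", "AG--CT"), "dna")
  ra <- realign_region(aln, 2, 4, align_params("DNA"))
  expect_identical(ra$rows, c("ACGT", "AGCT"))

  # a row that is empty inside the window comes back as all gaps
  aln2 <- msa_alignment(c("a", "b", "c"),
                        c("AAACCC", "AAA---", "AAAGGC"), "dna")
  ra2 <- realign_region(aln2, 3, 6, align_params("DNA"))
  expect_identical(substr(ra2$rows, 1, 3), rep("AAA", 3))
  expect_identical(gsub("-", "", ra2$rows[2]), "AAA")
})
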