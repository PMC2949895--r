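test_that("pair_index enumerates the upper triangle bijectively", {
  expect_equal(pair_index(0, 1, 3), 0)
  expect_equal(pair_index(0, 2, 3), 1)
  expect_equal(pair_index(1, 2, 3), 2)
  for (N in c(2, 5, 17, 50)) {
    ij <- pair_indices(N)
    idx <- pair_index(ij[, 1], ij[, 2], N)
    expect_identical(idx, as.numeric(0:(pair_count(N) - 1)))
  }
  expect_error(pair_index(2, 2, 5))
  expect_error(pair_index(1, 5, 5))
  # the big-family arithmetic stays exact in doubles
  expect_equal(pair_index(52748, 52749, 52750), 52750 * 52749 / 2 - 1)
})

test_that("store layout, diagonal and error contracts hold in both modes", {
  expect_error(store_create(1, "memory"), "N >= 2")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "matrix-file080.tmp")
  st <- store_create(3, "disk", path)
  expect_equal(file.size(path) - 20, 24)  # 3 cells x 8 bytes after header
  expect_equal(store_get(st, 1, 1), 0)
  expect_error(store_get(st, 0, 2), "incomplete matrix.*\\(0, 2\\)")
  store_put(st, 1, 2, 0.5)
  expect_equal(store_get(st, 2, 1), 0.5)
  expect_error(store_put(st, 0, 1, 1.5), "\\[0, 1\\]")
  expect_false(store_is_complete(st))
  store_close(st)
  expect_equal(store_required_bytes(400000), 20 + 8 * 400000 * 399999 / 2)
})

test_that("memory and disk backends agree cell-for-cell under random use", {
  withr::local_seed(5)
  N <- 12
  dir <- withr::local_tempdir()
  sm <- store_create(N, "memory")
  sd <- store_create(N, "disk", file.path(dir, "m.tmp"))
  ij <- pair_indices(N)
  vals <- runif(nrow(ij))
  for (k in sample(nrow(ij))) {          # random interleaving of puts
    store_put(sm, ij[k, 1], ij[k, 2], vals[k])
    store_put(sd, ij[k, 2], ij[k, 1], vals[k])  # swapped indices too
  }
  for (k in sample(nrow(ij)))
    expect_equal(store_get(sd, ij[k, 1], ij[k, 2]),
                 store_get(sm, ij[k, 1], ij[k, 2]))
  expect_true(store_is_complete(sm))
  expect_true(store_is_complete(sd))
  expect_identical(store_matrix(sd), store_matrix(sm))
  store_close(sd)
})

test_that("disk stores survive close and reopen", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.tmp")
  st <- store_create(5, "disk", path)
  ij <- pair_indices(5)
  for (k in seq_len(nrow(ij)))
    store_put(st, ij[k, 1], ij[k, 2], k / 10)
  store_close(st)
  back <- store_open(path)
  expect_equal(back$N, 5)
  for (k in seq_len(nrow(ij)))
    expect_equal(store_get(back, ij[k, 1], ij[k, 2]), k / 10)
  store_close(back)
  expect_error(store_open(file.path(dir, "nonesuch")))
})

test_that("pair spool writes canonical per-pair FASTA files", {
  set <- seq_set(c("a", "b", "c"), c("ACGT", "GGCC", "TTAA"))
  dir <- withr::local_tempdir()
  paths <- spool_pairs(set, dir)
  expect_identical(basename(list.files(dir)),
                   sprintf("pair-%09d.fa", 0:2))
  # pair P=1 is (a, c)
  two <- read_fasta(file.path(dir, "pair-000000001.fa"))
  expect_identical(two$ids, c("a", "c"))
  expect_identical(two$seqs, c("ACGT", "TTAA"))

  one <- seq_set("x", "ACGT")
  dir2 <- withr::local_tempdir()
  expect_length(spool_pairs(one, dir2), 0)
  expect_length(list.files(dir2), 0)

  # windowed generation: only a slice needs to exist
  dir3 <- withr::local_tempdir()
  spool_pairs(set, dir3, first = 1, last = 1)
  expect_identical(list.files(dir3), "pair-000000001.fa")
})
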