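test_that("self-scheduling matches hand-simulated assignments", {
  cfg2 <- scheduler_config("insta", 2)
  tr <- schedule_insta(rep(1, 6), cfg2)
  expect_equal(tr$makespan, 3)
  expect_equal(tr$idle_fraction, 0)

  tr <- schedule_insta(c(5, 1, 1, 1, 1, 1), cfg2)
  expect_equal(tr$makespan, 5)   # worker 0 holds the 5, worker 1 drains
  expect_equal(sort(tr$busy), c(5, 5))

  tr1 <- schedule_insta(c(3, 1, 4, 1, 5), scheduler_config("insta", 1))
  expect_equal(tr1$makespan, 14)  # serial limit

  expect_error(schedule_insta(c(1, -1), cfg2), "non-negative")
})

test_that("fixed-size chunks are dealt round-robin before execution", {
  tr <- schedule_fixed_chunk(c(5, 1, 1, 1, 1, 1),
                             scheduler_config("fixed_chunk", 2, 3))
  expect_equal(tr$makespan, 7)   # [5,1,1] vs [1,1,1]
  expect_equal(sort(tr$busy), c(3, 7))

  # degenerate chunk: everything lands on worker 0
  tr <- schedule_fixed_chunk(c(2, 2, 2), scheduler_config("fixed_chunk", 4, 10))
  expect_equal(tr$makespan, 6)
  expect_true(all(tr$assignments$worker == 0))

  # uniform work, unit chunks, divisible count: equal to self-scheduling
  ti <- schedule_insta(rep(2, 8), scheduler_config("insta", 4))
  tc <- schedule_fixed_chunk(rep(2, 8), scheduler_config("fixed_chunk", 4, 1))
  expect_equal(tc$makespan, ti$makespan)
})

test_that("policy comparison reports speedups and lower bounds", {
  tab <- compare_policies(c(5, 1, 1, 1, 1, 1), 2, chunk_size = 3)
  expect_equal(tab$speedup[tab$policy == "insta"], 2.0)
  expect_equal(tab$speedup[tab$policy == "fixed_chunk"], 10 / 7)

  withr::local_seed(8)
  for (rep in 1:20) {
    costs <- rlnorm(40, 0, 1.3)
    m <- sample(2:6, 1)
    tab <- compare_policies(costs, m)
    lb <- max(max(costs), sum(costs) / m)
    expect_true(all(tab$makespan >= lb - 1e-9))
  }
})

test_that("trace invariants hold on random instances", {
  withr::local_seed(42)
  for (rep in 1:25) {
    costs <- rlnorm(sample(5:60, 1), 0, 1)
    m <- sample(1:5, 1)
    expect_valid_trace(schedule_insta(costs, scheduler_config("insta", m)),
                       costs)
    expect_valid_trace(
      schedule_fixed_chunk(costs, scheduler_config("fixed_chunk", m)),
      costs)
  }
})

test_that("distance phase fills the store identically for every config", {
  set <- random_seq_set(8, c(10, 30), alphabet = "protein", seed = 6)
  p <- align_params("BLOSUM62")
  dir <- withr::local_tempdir()
  ref <- NULL
  for (policy in c("insta", "fixed_chunk")) {
    for (workers in c(1, 3)) {
      for (mode in c("memory", "disk")) {
        st <- if (mode == "memory") store_create(set$N, "memory") else
          store_create(set$N, "disk",
                       file.path(dir, sprintf("%s%d.tmp", policy, workers)))
        run_distance_phase(set, p, st,
                           scheduler_config(policy, workers))
        expect_equal(st$n_dispatched, pair_count(set$N))
        M <- store_matrix(st)
        if (is.null(ref)) ref <- M else expect_identical(M, ref)
        if (mode == "disk") store_close(st)
      }
    }
  }
})

test_that("distance phase works through a forked worker pool", {
  set <- random_seq_set(5, c(8, 15), seed = 77)
  p <- align_params("DNA")
  st1 <- store_create(5, "memory")
  run_distance_phase(set, p, st1, scheduler_config("insta", 2), "fork")
  st2 <- store_create(5, "memory")
  run_distance_phase(set, p, st2, scheduler_config("insta", 1), "serial")
  expect_identical(store_matrix(st1), store_matrix(st2))
})

test_that("a single pair job fills the one cell", {
  set <- random_seq_set(2, seed = 3)
  st <- store_create(2, "memory")
  run_distance_phase(set, align_params("DNA"), st)
  expect_true(store_is_complete(st))
  expect_equal(store_get(st, 0, 1),
               pairwise_distance(set$seqs[1], set$seqs[2],
                                 align_params("DNA")))
})
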