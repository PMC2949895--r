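# Shared fixtures and independent oracles built in code.

# small random sequence set
random_seq_set <- function(n, len_range = c(8, 20), alphabet = "dna",
                           seed = 1) {
  withr::with_seed(seed, {
    res <- alphabet_residues(alphabet, unknown = FALSE)
    seqs <- vapply(seq_len(n), function(k) {
      paste(sample(res, sample(len_range[1]:len_range[2], 1),
                   replace = TRUE), collapse = "")
    }, character(1))
    seq_set(sprintf("s%02d", seq_len(n)), seqs, alphabet = alphabet)
  })
}

# position-by-position affine score of two gapped rows: the independent
# recount used against DP scores and the vectorised SP total
score_gapped_pair <- function(row_a, row_b, params) {
  S <- params$matrix$scores
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  stopifnot(length(a) == length(b))
  s <- 0
  gap_a <- FALSE; gap_b <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" && b[k] == "-") next
    if (a[k] != "-" && b[k] != "-") {
      s <- s + S[a[k], b[k]]
      gap_a <- gap_b <- FALSE
    } else if (a[k] == "-") {
      s <- s - if (gap_a) params$gap_extend else
        params$gap_open + params$gap_extend
      gap_a <- TRUE; gap_b <- FALSE
    } else {
      s <- s - if (gap_b) params$gap_extend else
        params$gap_open + params$gap_extend
      gap_b <- TRUE; gap_a <- FALSE
    }
  }
  s
}

# brute-force optimal makespan over all worker assignments (small n only)
brute_force_opt_makespan <- function(costs, m) {
  n <- length(costs)
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    loads <- vapply(seq_len(m), function(w) sum(costs[grid[r, ] == w]),
                    numeric(1))
    best <- min(best, max(loads))
  }
  best
}

# check the structural invariants of a schedule trace
expect_valid_trace <- function(trace, costs) {
  df <- trace$assignments
  expect_setequal(df$P, seq_along(costs) - 1)
  expect_equal(nrow(df), length(costs))
  for (w in unique(df$worker)) {
    sub <- df[df$worker == w, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$finish[-nrow(sub)] - 1e-9))
  }
  expect_equal(trace$makespan, max(df$finish))
  busy <- sum(df$finish - df$start)
  if (trace$makespan > 0)
    expect_equal(trace$idle_fraction,
                 1 - busy / (trace$n_workers * trace$makespan))
}

# fill a store (memory) from a symmetric matrix scaled into [0, 1]
store_from_matrix <- function(D) {
  N <- nrow(D)
  st <- store_create(N, "memory")
  for (i in 0:(N - 2)) for (j in (i + 1):(N - 1))
    store_put(st, i, j, D[i + 1, j + 1])
  st
}
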