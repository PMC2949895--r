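# Stage (1): all-against-all pairwise distances into a distance store.

# compute one pair distance with a single retry, mirroring the master's
# requeue-once contract for failed workers
.compute_pair <- function(seqset, i, j, params, P) {
  once <- tryCatch(pairwise_distance(seqset$seqs[i + 1], seqset$seqs[j + 1],
                                     params),
                   error = function(e) e)
  if (!inherits(once, "error")) return(once)
  again <- tryCatch(pairwise_distance(seqset$seqs[i + 1], seqset$seqs[j + 1],
                                      params),
                    error = function(e) e)
  if (inherits(again, "error"))
    stop(sprintf("pair task P=%.0f (%d, %d) failed after retry: %s",
                 P, i, j, conditionMessage(again)))
  again
}

#' Run the distance phase over every sequence pair
#'
#' Computes [pairwise_distance()] for all `N(N-1)/2` pairs and writes each
#' result to the store keyed by `(i, j)`.  The scheduling policy and worker
#' count control only the order and grouping of the work; the final store
#' contents are identical for every configuration — the correctness
#' requirement that makes the phase safely parallelisable.
#'
#' @param seqset A [seq_set()] with `N >= 2`.
#' @param params An [align_params()].
#' @param store A [store_create()] result with matching `N`.
#' @param config A [scheduler_config()].
#' @param executor `"serial"` (master computes tasks in assignment order) or
#'   `"fork"` (a local process pool via the parallel package; one process
#'   per worker, honouring the same assignment contract).
#' @param progress Optional `function(done, total)` called roughly every 5%
#'   of the phase.
#' @return The store (now complete), with `store$n_dispatched` set to the
#'   number of tasks handed out.
#' @export
run_distance_phase <- function(seqset, params, store,
                               config = scheduler_config(),
                               executor = c("serial", "fork"),
                               progress = NULL) {
  executor <- match.arg(executor)
  stopifnot(inherits(seqset, "seq_set"), inherits(store, "dist_store"))
  if (store$N != seqset$N)
    stop("store was created for N = ", store$N, ", set has N = ", seqset$N)
  ij <- pair_indices(seqset$N)
  n <- nrow(ij)
  # assignment order: canonical for the dynamic policy, per-worker chunk
  # lists for the static one (observable only through computation order)
  ord <- if (config$policy == "fixed_chunk") {
    k <- .resolve_chunk_size(config, n)
    order(((seq_len(n) - 1L) %/% k) %% config$n_workers, seq_len(n))
  } else {
    seq_len(n)
  }
  run_one <- function(t) {
    .compute_pair(seqset, ij[t, 1], ij[t, 2], params, t - 1)
  }
  every <- max(1L, n %/% 20L)
  if (executor == "serial") {
    done <- 0L
    for (t in ord) {
      store_put(store, ij[t, 1], ij[t, 2], run_one(t))
      done <- done + 1L
      if (!is.null(progress) && (done %% every == 0L || done == n))
        progress(done, n)
    }
  } else {
    if (!requireNamespace("parallel", quietly = TRUE))
      stop("the fork executor needs the parallel package")
    d <- parallel::mclapply(ord, run_one, mc.cores = config$n_workers,
                            mc.preschedule = config$policy == "fixed_chunk")
    for (k in seq_along(ord)) {
      if (inherits(d[[k]], c("try-error", "error")))
        stop("pair task P=", ord[k] - 1, " failed in worker pool")
      store_put(store, ij[ord[k], 1], ij[ord[k], 2], d[[k]])
    }
    if (!is.null(progress)) progress(n, n)
  }
  store$n_dispatched <- n
  store
}
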