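# Master-worker distribution of pair tasks.
#
# Two policies:
#  * "insta"       — idle-worker self-scheduling: every worker holds exactly
#                    one task; the moment it finishes it receives the next
#                    unassigned task (the dynamic policy that keeps workers
#                    busy when task costs are highly non-uniform).
#  * "fixed_chunk" — tasks are pre-partitioned in canonical order into
#                    consecutive chunks of fixed size, dealt round-robin to
#                    workers before execution (static assignment, the
#                    classic MPI-era policy whose imbalance the dynamic
#                    policy removes).

#' Scheduler configuration
#'
#' @param policy `"insta"` or `"fixed_chunk"`.
#' @param n_workers Positive worker count.
#' @param chunk_size Fixed-chunk only: tasks per chunk.  Default
#'   `ceiling(n_tasks / (5 * n_workers))`, resolved when scheduling.
#' @param seed Integer seed recorded with the run.
#' @return Object of class `scheduler_config`.
#' @export
scheduler_config <- function(policy = c("insta", "fixed_chunk"),
                             n_workers = 1L, chunk_size = NULL, seed = 1L) {
  policy <- match.arg(policy)
  n_workers <- as.integer(n_workers)
  if (n_workers < 1L) stop("n_workers must be >= 1")
  if (!is.null(chunk_size) && chunk_size < 1L)
    stop("chunk_size must be >= 1")
  structure(list(policy = policy, n_workers = n_workers,
                 chunk_size = chunk_size, seed = as.integer(seed)),
            class = "scheduler_config")
}

#' Build pair tasks from costs
#'
#' @param costs Non-negative numeric vector of task durations.
#' @param P Pair sequence numbers (default `0 .. length(costs) - 1`).
#' @return data.frame with columns `P` and `cost` in canonical order.
#' @export
pair_tasks <- function(costs, P = seq_along(costs) - 1) {
  costs <- as.numeric(costs)
  if (!length(costs)) stop("tasks must be non-empty")
  if (any(!is.finite(costs)) || any(costs < 0))
    stop("task costs must be non-negative")
  data.frame(P = as.numeric(P), cost = costs)
}

.resolve_chunk_size <- function(config, n_tasks) {
  if (!is.null(config$chunk_size)) return(as.integer(config$chunk_size))
  max(1L, as.integer(ceiling(n_tasks / (5 * config$n_workers))))
}

.new_trace <- function(assign_df, n_workers, policy, chunk_size = NA) {
  makespan <- if (nrow(assign_df)) max(assign_df$finish) else 0
  busy <- vapply(0:(n_workers - 1), function(w)
    sum(assign_df$finish[assign_df$worker == w] -
          assign_df$start[assign_df$worker == w]), numeric(1))
  idle <- if (makespan > 0) 1 - sum(busy) / (n_workers * makespan) else 0
  structure(list(assignments = assign_df, n_workers = n_workers,
                 policy = policy, chunk_size = chunk_size,
                 makespan = makespan, busy = busy, idle_fraction = idle),
            class = "schedule_trace")
}

#' @export
print.schedule_trace <- function(x, ...) {
  cat(sprintf("schedule_trace: %s, %d tasks on %d workers, makespan %.4g, idle %.1f%%\n",
              x$policy, nrow(x$assignments), x$n_workers, x$makespan,
              100 * x$idle_fraction))
  invisible(x)
}

#' Simulate idle-worker self-scheduling (one task per request)
#'
#' Discrete-event simulation: at t = 0 each worker receives one task in
#' canonical order; whenever a worker finishes it immediately receives the
#' next unassigned task; ties go to the lowest worker index.
#'
#' @param tasks A [pair_tasks()] data.frame (or bare cost vector).
#' @param config A [scheduler_config()] with `policy = "insta"`.
#' @return A `schedule_trace`: per-task `(worker, P, start, finish)`,
#'   `makespan`, per-worker `busy` time and `idle_fraction`.
#' @export
#' @examples
#' schedule_insta(rep(1, 6), scheduler_config("insta", n_workers = 2))$makespan
schedule_insta <- function(tasks, config) {
  if (!is.data.frame(tasks)) tasks <- pair_tasks(tasks)
  stopifnot(inherits(config, "scheduler_config"))
  if (config$policy != "insta") stop("config$policy must be 'insta'")
  n <- nrow(tasks); m <- config$n_workers
  if (any(tasks$cost < 0)) stop("task costs must be non-negative")
  avail <- numeric(m)          # next time each worker is free
  worker <- integer(n); start <- numeric(n)
  for (k in seq_len(n)) {
    w <- which.min(avail)      # lowest index wins ties
    worker[k] <- w - 1L
    start[k] <- avail[w]
    avail[w] <- avail[w] + tasks$cost[k]
  }
  .new_trace(data.frame(worker = worker, P = tasks$P, start = start,
                        finish = start + tasks$cost),
             m, "insta")
}

#' Simulate static fixed-size chunk scheduling
#'
#' Tasks are split in canonical order into consecutive chunks of
#' `chunk_size`; chunks are dealt round-robin to workers before execution
#' and each worker runs its chunks back to back from t = 0.
#'
#' @param tasks A [pair_tasks()] data.frame (or bare cost vector).
#' @param config A [scheduler_config()] with `policy = "fixed_chunk"`.
#' @return A `schedule_trace`.
#' @export
schedule_fixed_chunk <- function(tasks, config) {
  if (!is.data.frame(tasks)) tasks <- pair_tasks(tasks)
  stopifnot(inherits(config, "scheduler_config"))
  if (config$policy != "fixed_chunk")
    stop("config$policy must be 'fixed_chunk'")
  n <- nrow(tasks); m <- config$n_workers
  if (any(tasks$cost < 0)) stop("task costs must be non-negative")
  k <- .resolve_chunk_size(config, n)
  chunk <- (seq_len(n) - 1L) %/% k
  worker <- chunk %% m
  start <- numeric(n)
  avail <- numeric(m)
  for (t in seq_len(n)) {
    w <- worker[t] + 1L
    start[t] <- avail[w]
    avail[w] <- avail[w] + tasks$cost[t]
  }
  .new_trace(data.frame(worker = worker, P = tasks$P, start = start,
                        finish = start + tasks$cost),
             m, "fixed_chunk", k)
}

#' Compare scheduling policies over a worker sweep
#'
#' @param task_costs Non-negative cost vector.
#' @param n_workers_list Worker counts to sweep.
#' @param chunk_size Fixed-chunk size (`NULL` for the default rule).
#' @return data.frame `(n_workers, policy, makespan, speedup,
#'   idle_fraction)`, where speedup is serial total work / makespan.
#' @export
#' @examples
#' compare_policies(c(5, 1, 1, 1, 1, 1), 2, chunk_size = 3)
compare_policies <- function(task_costs, n_workers_list, chunk_size = NULL) {
  tasks <- pair_tasks(task_costs)
  serial <- sum(tasks$cost)
  rows <- lapply(as.integer(n_workers_list), function(m) {
    ti <- schedule_insta(tasks, scheduler_config("insta", m))
    tc <- schedule_fixed_chunk(tasks,
            scheduler_config("fixed_chunk", m, chunk_size = chunk_size))
    data.frame(n_workers = m,
               policy = c("insta", "fixed_chunk"),
               makespan = c(ti$makespan, tc$makespan),
               speedup = serial / c(ti$makespan, tc$makespan),
               idle_fraction = c(ti$idle_fraction, tc$idle_fraction))
  })
  do.call(rbind, rows)
}

#' Export a schedule trace as tab-separated values
#'
#' @param trace A `schedule_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(trace$assignments[, c("worker", "P", "start", "finish")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulated pair-task costs from sequence lengths
#'
#' The dynamic-programming work for a pair is proportional to the product
#' of the two sequence lengths; costs are scaled to unit mean.
#'
#' @param seqset A [seq_set()].
#' @return A [pair_tasks()] data.frame over all pairs in canonical order.
#' @export
task_costs_from_lengths <- function(seqset) {
  len <- nchar(seqset$seqs)
  ij <- pair_indices(seqset$N)
  costs <- len[ij[, 1] + 1L] * len[ij[, 2] + 1L]
  pair_tasks(costs / mean(costs))
}
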