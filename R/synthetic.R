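# Seeded generators: sequence families and scheduler task-cost sets.

# mean of a log-normal truncated to [lo, hi]
.trunc_lnorm_mean <- function(meanlog, sdlog, lo, hi) {
  a <- (log(lo) - meanlog) / sdlog
  b <- (log(hi) - meanlog) / sdlog
  num <- pnorm(b - sdlog) - pnorm(a - sdlog)
  den <- pnorm(b) - pnorm(a)
  exp(meanlog + sdlog^2 / 2) * num / den
}

#' Synthetic family model
#'
#' Parameters of the sequence-family generator.  Lengths follow a
#' log-normal truncated to `[min_length, max_length]` whose location is
#' fitted so the truncated mean hits `mean_length`; defaults emulate a
#' large, divergent protein superfamily (mean 440 aa, lengths 10-11600).
#' Each sequence derives from a common random ancestor by per-site point
#' substitutions and geometric-length indels, then has its length adjusted
#' to its own draw from the length law.
#'
#' @param n_sequences Number of sequences to generate.
#' @param mean_length Target mean sequence length (residues).
#' @param min_length,max_length Hard length bounds.
#' @param sdlog Log-scale spread of the length law.
#' @param sub_rate Per-site substitution probability.
#' @param indel_rate Per-site indel event probability.
#' @param indel_geom_p Geometric parameter of indel lengths (mean
#'   `1/p - 1 + 1` columns per event).
#' @param alphabet `"protein"` or `"dna"`.
#' @param seed Integer seed; the same seed reproduces the family exactly.
#' @return Object of class `family_model`.
#' @export
family_model <- function(n_sequences = 100L, mean_length = 440,
                         min_length = 10, max_length = 11600,
                         sdlog = 0.6, sub_rate = 0.3, indel_rate = 0.05,
                         indel_geom_p = 0.3,
                         alphabet = c("protein", "dna"), seed = 1L) {
  alphabet <- match.arg(alphabet)
  if (min_length > max_length) stop("min_length must be <= max_length")
  if (mean_length < min_length || mean_length > max_length)
    stop("mean_length must lie within [min_length, max_length]")
  fit <- if (min_length == max_length) {
    list(root = log(min_length))
  } else {
    uniroot(function(m)
      .trunc_lnorm_mean(m, sdlog, min_length, max_length) - mean_length,
      lower = log(min_length), upper = log(max_length), tol = 1e-10)
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 mean_length = mean_length, min_length = min_length,
                 max_length = max_length, sdlog = sdlog,
                 meanlog = fit$root, sub_rate = sub_rate,
                 indel_rate = indel_rate, indel_geom_p = indel_geom_p,
                 alphabet = alphabet, seed = as.integer(seed)),
            class = "family_model")
}

# one truncated log-normal length draw per sequence
.draw_lengths <- function(model, n) {
  if (model$min_length == model$max_length)
    return(rep(model$min_length, n))
  lo <- plnorm(model$min_length, model$meanlog, model$sdlog)
  hi <- plnorm(model$max_length, model$meanlog, model$sdlog)
  len <- round(qlnorm(runif(n, lo, hi), model$meanlog, model$sdlog))
  pmin(pmax(len, model$min_length), model$max_length)
}

#' Generate a synthetic sequence family
#'
#' Draws a random ancestor at the model's mean length, evolves each family
#' member by point substitutions (always to a different residue) and
#' geometric-length insertions/deletions, then trims or pads the result to
#' the member's own length draw.  Deterministic under the model's seed.
#'
#' @param model A [family_model()].
#' @return A [seq_set()] with ids `seq000001 ...`.
#' @export
#' @examples
#' fam <- gen_family(family_model(n_sequences = 5, mean_length = 50,
#'                                max_length = 200, seed = 42))
gen_family <- function(model) {
  stopifnot(inherits(model, "family_model"))
  res <- alphabet_residues(model$alphabet, unknown = FALSE)
  withr::with_seed(model$seed, {
    anc <- sample(res, round(model$mean_length), replace = TRUE)
    lens <- .draw_lengths(model, model$n_sequences)
    seqs <- vapply(seq_len(model$n_sequences), function(k) {
      s <- anc
      # point substitutions, always to a different residue
      hit <- which(runif(length(s)) < model$sub_rate)
      if (length(hit)) {
        shift <- sample.int(length(res) - 1L, length(hit), replace = TRUE)
        s[hit] <- res[(match(s[hit], res) - 1L + shift) %% length(res) + 1L]
      }
      # indel events at random anchor sites
      n_ev <- rbinom(1L, length(s), model$indel_rate)
      if (n_ev > 0) {
        for (e in seq_len(n_ev)) {
          l <- rgeom(1L, model$indel_geom_p) + 1L
          at <- sample.int(length(s), 1L)
          if (runif(1) < 0.5) {
            s <- s[-(at:min(at + l - 1L, length(s)))]
            if (!length(s)) s <- sample(res, 1L)
          } else {
            s <- append(s, sample(res, l, replace = TRUE), after = at)
          }
        }
      }
      # adjust to this member's length draw (centred trim / random pad)
      L <- lens[k]
      if (length(s) > L) {
        off <- (length(s) - L) %/% 2L
        s <- s[(off + 1L):(off + L)]
      } else if (length(s) < L) {
        s <- c(s, sample(res, L - length(s), replace = TRUE))
      }
      paste(s, collapse = "")
    }, character(1))
    seq_set(sprintf("seq%06d", seq_len(model$n_sequences)), seqs,
            alphabet = model$alphabet)
  })
}

#' Generate synthetic task costs
#'
#' Seeded draws of non-negative task durations for scheduling experiments.
#'
#' @param n_tasks Number of costs.
#' @param distribution `"uniform"`, `"lognormal"` or `"pareto"`.
#' @param seed Integer seed.
#' @param min,max Uniform bounds.
#' @param meanlog,sdlog Log-normal parameters.
#' @param alpha,xmin Pareto shape (> 0) and scale (> 0); the analytic mean
#'   `alpha * xmin / (alpha - 1)` exists for `alpha > 1`.
#' @return Numeric cost vector with a `summary` attribute (mean, sd, max).
#' @export
#' @examples
#' gen_task_costs(4, "uniform", seed = 1, min = 1, max = 1)
gen_task_costs <- function(n_tasks,
                           distribution = c("uniform", "lognormal", "pareto"),
                           seed = 1L, min = 0.5, max = 1.5, meanlog = 0,
                           sdlog = 1, alpha = 2.5, xmin = 1) {
  distribution <- match.arg(distribution)
  n_tasks <- as.integer(n_tasks)
  if (n_tasks < 1L) stop("n_tasks must be >= 1")
  costs <- withr::with_seed(as.integer(seed), {
    switch(distribution,
      uniform = {
        if (min < 0 || max < min) stop("need 0 <= min <= max")
        runif(n_tasks, min, max)
      },
      lognormal = {
        if (sdlog < 0) stop("sdlog must be >= 0")
        rlnorm(n_tasks, meanlog, sdlog)
      },
      pareto = {
        if (alpha <= 0 || xmin <= 0) stop("need alpha > 0 and xmin > 0")
        xmin / runif(n_tasks)^(1 / alpha)
      })
  })
  attr(costs, "summary") <- c(mean = mean(costs), sd = sd(costs),
                              max = max(costs))
  costs
}
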