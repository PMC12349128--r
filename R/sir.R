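# Deterministic sub-stream seeds: mixes a base seed with up to two indices
# so per-node / per-repetition runs are reproducible and order-independent.
# All arithmetic stays exact in doubles (< 2^53) and the result fits a
# 32-bit R integer.
derive_seed <- function(seed, a = 0, b = 0) {
  s <- (abs(seed) %% 2147483647) * 48271 + a * 1299721 + b * 7919
  as.integer(s %% 2147483646) + 1L
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Integer adjacency list for the hot simulation loop.
adjacency_index <- function(g) {
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

# Core synchronous SIR loop on an integer adjacency list. Returns the
# vector of susceptible counts per step (index 1 = step 0) plus whether
# the epidemic had died before max_steps. status: 0 S, 1 I, 2 R.
sir_core <- function(adj, n, seed_idx, alpha, beta, max_steps) {
  status <- integer(n)
  status[seed_idx] <- 1L
  s_counts <- integer(max_steps + 1L)
  i_counts <- integer(max_steps + 1L)
  r_counts <- integer(max_steps + 1L)
  s_counts[1L] <- n - length(seed_idx)
  i_counts[1L] <- length(seed_idx)
  steps <- 0L
  for (t in seq_len(max_steps)) {
    infected <- which(status == 1L)
    if (length(infected) == 0L) break
    contacts <- unlist(adj[infected], use.names = FALSE)
    contacts <- contacts[status[contacts] == 0L]
    if (length(contacts) > 0L) {
      k <- tabulate(contacts, nbins = n)
      cand <- which(k > 0L)
      p <- 1 - (1 - alpha)^k[cand]
      newly <- cand[stats::runif(length(cand)) < p]
      status[newly] <- 1L
    }
    # recovery applies only to nodes infectious at the start of the step,
    # so a newly infected node gets at least one infectious step
    recovered <- infected[stats::runif(length(infected)) < beta]
    status[recovered] <- 2L
    steps <- t
    s_counts[t + 1L] <- sum(status == 0L)
    i_counts[t + 1L] <- sum(status == 1L)
    r_counts[t + 1L] <- n - s_counts[t + 1L] - i_counts[t + 1L]
  }
  list(S = s_counts[seq_len(steps + 1L)],
       I = i_counts[seq_len(steps + 1L)],
       R = r_counts[seq_len(steps + 1L)],
       steps = steps)
}

#' One stochastic SIR run
#'
#' Discrete-time susceptible-infected-recovered spreading with synchronous
#' updates: at each step every infected node independently infects each
#' susceptible neighbor with probability \code{alpha}, then every node that
#' was infectious at the start of the step recovers with probability
#' \code{beta}. A newly infected node therefore gets at least one
#' infectious step even at \code{beta = 1}. The run stops when no infected
#' nodes remain or \code{max_steps} is reached. Fully reproducible given
#' \code{seed}.
#'
#' @param g an igraph graph.
#' @param seeds non-empty character vector of initially infected nodes.
#' @param alpha infection probability per infected-susceptible contact per
#'   step, in [0, 1].
#' @param beta recovery probability per step, in [0, 1].
#' @param max_steps time horizon.
#' @param seed integer RNG seed for this run.
#' @return an object of class \code{"sir_outcome"}: \code{counts}
#'   (data.frame step/S/I/R, starting at step 0), \code{final_size}
#'   (|I| + |R| at termination), \code{steps_run}.
#' @export
sir_run <- function(g, seeds, alpha, beta = 1, max_steps = 100L, seed = 1L) {
  stopifnot(igraph::is_igraph(g),
            alpha >= 0, alpha <= 1, beta >= 0, beta <= 1, max_steps >= 1)
  if (length(seeds) == 0L) stop("seed set must be non-empty")
  nms <- igraph::V(g)$name
  seed_idx <- match(seeds, nms)
  if (anyNA(seed_idx)) {
    stop(sprintf("unknown seed node(s): %s",
                 paste(seeds[is.na(seed_idx)], collapse = ", ")))
  }
  n <- igraph::vcount(g)
  adj <- adjacency_index(g)
  res <- with_seed(seed,
                   sir_core(adj, n, seed_idx, alpha, beta, max_steps))
  counts <- data.frame(step = seq_along(res$S) - 1L,
                       S = res$S, I = res$I, R = res$R)
  structure(list(counts = counts,
                 final_size = n - res$S[length(res$S)],
                 steps_run = res$steps,
                 params = list(alpha = alpha, beta = beta,
                               max_steps = max_steps, seed = seed)),
            class = "sir_outcome")
}

#' @export
print.sir_outcome <- function(x, ...) {
  cat(sprintf(
    "SIR run: alpha = %g, beta = %g; %d step(s), final size %d\n",
    x$params$alpha, x$params$beta, x$steps_run, x$final_size))
  invisible(x)
}

#' Spreading power of a single node
#'
#' Mean final epidemic size (infected + recovered) over \code{reps}
#' independent SIR runs seeded at one node -- the ground-truth influence
#' used to validate centrality rankings. Each repetition runs on a
#' deterministic sub-stream derived from \code{seed} and the repetition
#' index.
#'
#' @inheritParams sir_run
#' @param node the single seed node.
#' @param reps number of Monte-Carlo repetitions.
#' @return numeric mean final size.
#' @export
spreading_power <- function(g, node, alpha, beta = 1, max_steps = 100L,
                            reps = 1000L, seed = 1L) {
  stopifnot(reps >= 1)
  nms <- igraph::V(g)$name
  idx <- match(node, nms)
  if (is.na(idx) || length(node) != 1L) {
    stop("spreading_power takes exactly one known seed node")
  }
  n <- igraph::vcount(g)
  adj <- adjacency_index(g)
  sizes <- vapply(seq_len(reps), function(r) {
    res <- with_seed(derive_seed(seed, 0, r),
                     sir_core(adj, n, idx, alpha, beta, max_steps))
    n - res$S[length(res$S)]
  }, 0)
  mean(sizes)
}

#' Rank all nodes by SIR spreading power
#'
#' Computes every node's \code{\link{spreading_power}} on a per-node
#' deterministic sub-stream and ranks descending with the shared tie rule.
#'
#' @inheritParams spreading_power
#' @return a \code{"node_ranking"} whose \code{score} column is the mean
#'   final epidemic size.
#' @export
rank_by_sir <- function(g, alpha, beta = 1, max_steps = 100L,
                        reps = 1000L, seed = 1L) {
  stopifnot(igraph::is_igraph(g), igraph::vcount(g) >= 1L)
  nms <- igraph::V(g)$name
  n <- igraph::vcount(g)
  adj <- adjacency_index(g)
  powers <- vapply(seq_len(n), function(i) {
    node_seed <- derive_seed(seed, i, 0)
    sizes <- vapply(seq_len(reps), function(r) {
      res <- with_seed(derive_seed(node_seed, 0, r),
                       sir_core(adj, n, i, alpha, beta, max_steps))
      n - res$S[length(res$S)]
    }, 0)
    mean(sizes)
  }, 0)
  names(powers) <- nms
  make_ranking(powers, method = sprintf("sir(alpha=%g,beta=%g)", alpha, beta))
}

#' Mean epidemic-size curve for a seed set
#'
#' Seeds the SIR process at a given node set and reports the mean number
#' of ever-infected nodes (infected + recovered) at each time step
#' \code{t = 1..max_steps}, averaged over repetitions. After an epidemic
#' dies out its final size carries forward, so the curve is non-decreasing.
#'
#' @inheritParams sir_run
#' @param reps number of Monte-Carlo repetitions.
#' @return data.frame with columns \code{step} and \code{F} (mean
#'   infected + recovered).
#' @export
topk_curve <- function(g, seeds, alpha, beta = 1, max_steps = 30L,
                       reps = 1000L, seed = 1L) {
  stopifnot(reps >= 1)
  if (length(seeds) == 0L) stop("seed set must be non-empty")
  nms <- igraph::V(g)$name
  seed_idx <- match(seeds, nms)
  if (anyNA(seed_idx)) {
    stop(sprintf("unknown seed node(s): %s",
                 paste(seeds[is.na(seed_idx)], collapse = ", ")))
  }
  n <- igraph::vcount(g)
  adj <- adjacency_index(g)
  acc <- numeric(max_steps)
  for (r in seq_len(reps)) {
    res <- with_seed(derive_seed(seed, 0, r),
                     sir_core(adj, n, seed_idx, alpha, beta, max_steps))
    infected_ever <- n - res$S       # index 1 = step 0
    f <- numeric(max_steps)
    upto <- min(res$steps, max_steps)
    if (upto >= 1) f[seq_len(upto)] <- infected_ever[1 + seq_len(upto)]
    if (upto < max_steps) {
      f[(upto + 1):max_steps] <- infected_ever[length(infected_ever)]
    }
    acc <- acc + f
  }
  data.frame(step = seq_len(max_steps), F = acc / reps)
}
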