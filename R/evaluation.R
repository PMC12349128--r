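#' Kendall tau rank agreement with explicit tie handling
#'
#' Pairwise concordance statistic
#' \eqn{\tau = 2(m_c - m_d) / (m(m-1))} over all unordered node pairs of
#' two score sets on the same nodes. A pair tied in either input counts
#' toward neither the concordant count \eqn{m_c} nor the discordant count
#' \eqn{m_d} but remains in the denominator -- this is deliberately NOT
#' the tau-b tie correction a statistics library applies; on tie-free
#' inputs the two coincide.
#'
#' @param scores_a,scores_b named numeric vectors over identical node sets
#'   (any order), length >= 2.
#' @param counts logical; if \code{TRUE} return the pair counts as well.
#' @return numeric tau in [-1, 1], or (with \code{counts = TRUE}) a list
#'   with \code{tau}, \code{concordant}, \code{discordant}, \code{pairs}.
#' @export
kendall_tau <- function(scores_a, scores_b, counts = FALSE) {
  if (is.null(names(scores_a)) || is.null(names(scores_b))) {
    stop("both score vectors must be named by node")
  }
  if (!setequal(names(scores_a), names(scores_b)) ||
      length(scores_a) != length(scores_b)) {
    stop("score vectors must cover identical node sets")
  }
  m <- length(scores_a)
  if (m < 2L) stop("kendall_tau requires at least 2 nodes")
  b <- scores_b[names(scores_a)]
  sa <- sign(outer(scores_a, scores_a, "-"))
  sb <- sign(outer(b, b, "-"))
  prod <- (sa * sb)[upper.tri(sa)]
  mc <- sum(prod > 0)
  md <- sum(prod < 0)
  tau <- 2 * (mc - md) / (m * (m - 1))
  if (counts) {
    list(tau = tau, concordant = mc, discordant = md,
         pairs = m * (m - 1) / 2)
  } else {
    tau
  }
}

#' Top-m Jaccard consistency of two rankings
#'
#' Intersection-over-union of the two top-m node sets:
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}. 1 means the two methods agree
#' exactly on who the m key nodes are; 0 means disjoint sets.
#'
#' @param rank_a,rank_b \code{"node_ranking"} tables (or character vectors
#'   already in rank order).
#' @param m number of top nodes to compare; at most the length of both.
#' @return numeric in [0, 1]; symmetric in its arguments.
#' @export
jaccard_topm <- function(rank_a, rank_b, m) {
  a <- if (is.character(rank_a)) rank_a else rank_a$node
  b <- if (is.character(rank_b)) rank_b else rank_b$node
  if (m < 1L || m > length(a) || m > length(b)) {
    stop("m must be between 1 and the length of both rankings")
  }
  top_a <- a[seq_len(m)]
  top_b <- b[seq_len(m)]
  length(intersect(top_a, top_b)) / length(union(top_a, top_b))
}

#' Kendall tau sweep over an infection-probability grid
#'
#' For each infection probability in \code{alphas}, computes the SIR
#' ground-truth spreading power of every node once, then the Kendall tau
#' of each method's scores against it -- the shape of the published
#' per-network tau tables.
#'
#' @param g an igraph graph.
#' @param methods named list; each element is either a named numeric score
#'   vector over the nodes of \code{g}, or a function \code{g ->} such a
#'   vector.
#' @param alphas numeric vector of infection probabilities in [0, 1].
#' @param beta,max_steps,reps,seed SIR parameters (see
#'   \code{\link{rank_by_sir}}).
#' @return data.frame with one row per alpha and one tau column per
#'   method, plus the SIR concordant/discordant pair counts are available
#'   through \code{kendall_tau(..., counts = TRUE)} on the stored scores
#'   in \code{attr(, "sir_scores")}.
#' @export
tau_sweep <- function(g, methods, alphas, beta = 1, max_steps = 100L,
                      reps = 1000L, seed = 1L) {
  stopifnot(length(alphas) >= 1, all(alphas >= 0), all(alphas <= 1))
  if (is.null(names(methods)) || any(!nzchar(names(methods)))) {
    stop("'methods' must be a named list")
  }
  method_scores <- lapply(methods, function(m) {
    s <- if (is.function(m)) m(g) else m
    if (is.null(names(s))) stop("method scores must be named by node")
    s
  })
  sir_scores <- list()
  rows <- lapply(seq_along(alphas), function(i) {
    rk <- rank_by_sir(g, alpha = alphas[i], beta = beta,
                      max_steps = max_steps, reps = reps,
                      seed = derive_seed(seed, i, 0))
    truth <- stats::setNames(rk$score, rk$node)
    sir_scores[[i]] <<- truth
    taus <- vapply(method_scores, function(s) kendall_tau(s, truth), 0)
    c(alpha = alphas[i], taus)
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "sir_scores") <- stats::setNames(sir_scores, alphas)
  out
}

#' Spreading power in a method's rank order
#'
#' Lists ground-truth spreading powers in the order a method ranked the
#' nodes. For a perfect method the series is non-increasing; bumps mark
#' nodes the method over- or under-ranked.
#'
#' @param rank a \code{"node_ranking"} table (or character vector of nodes
#'   in rank order).
#' @param powers named numeric vector of spreading powers covering every
#'   ranked node.
#' @return data.frame with columns \code{rank_index}, \code{node},
#'   \code{power}.
#' @export
ranked_infectivity <- function(rank, powers) {
  nodes <- if (is.character(rank)) rank else rank$node
  missing <- setdiff(nodes, names(powers))
  if (length(missing) > 0) {
    stop(sprintf("no spreading power for node(s): %s",
                 paste(missing, collapse = ", ")))
  }
  data.frame(rank_index = seq_along(nodes), node = nodes,
             power = unname(powers[nodes]), stringsAsFactors = FALSE)
}
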