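#' Classical centrality baselines
#'
#' Deterministic node rankings by the classical centralities the influence
#' literature compares against: degree, k-shell, closeness, betweenness,
#' eigenvector and PageRank. All use the same tie rule as
#' \code{\link{ranking}} (descending score, then ascending identifier).
#'
#' Conventions on disconnected graphs: closeness is computed within
#' connected components -- a node's score is the number of other nodes it
#' can reach divided by the sum of shortest-path distances to them, and 0
#' for isolated nodes. PageRank uses damping 0.85; eigenvector centrality
#' uses ARPACK and errors if the iteration cap is hit without convergence.
#'
#' @param g an igraph graph.
#' @param method one of \code{"degree"}, \code{"kshell"},
#'   \code{"closeness"}, \code{"betweenness"}, \code{"eigenvector"},
#'   \code{"pagerank"}.
#' @param damping PageRank damping factor.
#' @param eigen_maxiter iteration cap for eigenvector centrality.
#' @return a \code{"node_ranking"} data.frame (node, score, rank).
#' @export
rank_centrality <- function(g,
                            method = c("degree", "kshell", "closeness",
                                       "betweenness", "eigenvector",
                                       "pagerank"),
                            damping = 0.85,
                            eigen_maxiter = 3000L) {
  method <- match.arg(method)
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) stop("cannot rank an empty graph")
  nms <- igraph::V(g)$name
  scores <- switch(
    method,
    degree = {
      s <- as.numeric(igraph::degree(g)); names(s) <- nms; s
    },
    kshell = as.numeric(kshell(g)),
    closeness = component_closeness(g),
    betweenness = {
      s <- igraph::betweenness(g, directed = FALSE); names(s) <- nms; s
    },
    eigenvector = {
      res <- igraph::eigen_centrality(
        g, directed = FALSE,
        options = list(maxiter = eigen_maxiter)
      )
      if (!is.null(res$options$info) && res$options$info != 0) {
        stop(sprintf(
          "eigenvector centrality did not converge within %d iterations",
          eigen_maxiter))
      }
      s <- res$vector; names(s) <- nms; s
    },
    pagerank = {
      s <- igraph::page_rank(g, damping = damping)$vector
      names(s) <- nms; s
    }
  )
  if (method == "kshell") names(scores) <- nms
  make_ranking(scores, method = method)
}

# Within-component closeness: (# reachable others) / (sum of distances to
# them); isolated nodes score 0.
component_closeness <- function(g) {
  nms <- igraph::V(g)$name
  d <- igraph::distances(g)
  diag(d) <- Inf
  s <- apply(d, 1, function(row) {
    finite <- is.finite(row)
    if (!any(finite)) 0 else sum(finite) / sum(row[finite])
  })
  names(s) <- nms
  s
}
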