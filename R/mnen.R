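#' Self-influence of a node
#'
#' A node's stand-alone importance: the sum of its k-shell index and its
#' degree, \eqn{SI(v) = Ks(v) + d(v)}. Both inputs are non-negative
#' integers from the graph being scored.
#'
#' @param kshell non-negative integer k-shell index (vectorised).
#' @param degree non-negative integer degree (vectorised).
#' @return numeric self-influence value(s).
#' @examples
#' self_influence(3, 6) # 9
#' @export
self_influence <- function(kshell, degree) {
  stopifnot(all(kshell >= 0), all(degree >= 0), all(kshell <= degree))
  kshell + degree
}

#' Log-damped k-shell contribution term
#'
#' The self-term of a neighbor node: its k-shell index raised to the power
#' \eqn{\log_{10}(d) / k_{max}}. The logarithm damps the degree so that
#' raw degree (often orders of magnitude larger than the shell index) does
#' not dominate the contribution. \code{Ks = 0} with \code{d = 1} returns 1
#' by the \eqn{0^0 = 1} convention; any other \code{Ks = 0} returns 0
#' (unreachable on a real graph, where \code{d >= 1} implies \code{Ks >= 1}).
#'
#' @param ks non-negative integer k-shell index.
#' @param d positive integer degree.
#' @param kmax positive integer, the maximum degree of the graph.
#' @return numeric; >= 1 whenever \code{ks >= 1} and \code{d >= 1}.
#' @examples
#' gamma_term(3, 5, 6) # 1.1365..., prints as 1.137 to 3 d.p.
#' @export
gamma_term <- function(ks, d, kmax) {
  stopifnot(all(ks >= 0))
  if (any(d < 1)) stop("gamma_term requires degree >= 1 (log of zero)")
  if (any(kmax < 1)) stop("gamma_term requires kmax >= 1")
  ks^(log10(d) / kmax)
}

#' Common neighbors of two nodes
#'
#' \eqn{CN(v_i, v_j) = Nei(v_i) \cap Nei(v_j)}; contains neither node.
#'
#' @param g an igraph graph.
#' @param vi,vj distinct node identifiers.
#' @return character vector of common neighbor names.
#' @export
common_neighbors <- function(g, vi, vj) {
  if (identical(vi, vj)) stop("common_neighbors requires two distinct nodes")
  intersect(node_neighbors(g, vi), node_neighbors(g, vj))
}

#' Exclusive neighborhood of a neighbor node
#'
#' The neighbors of \code{vj} that are not common neighbors of \code{vi}
#' and \code{vj}: \eqn{EN(v_i, v_j) = Nei(v_j) - CN(v_i, v_j)}. Because
#' \code{vj} is adjacent to \code{vi}, the set always contains \code{vi}
#' itself (it is in \eqn{Nei(v_j)} but never in the intersection), which
#' guards against an empty exclusive neighborhood.
#'
#' @param g an igraph graph.
#' @param vi a node identifier.
#' @param vj a neighbor of \code{vi}.
#' @return character vector: the private second-hop territory \code{vj}
#'   contributes to \code{vi}, plus \code{vi} itself.
#' @export
exclusive_neighborhood <- function(g, vi, vj) {
  nj <- node_neighbors(g, vj)
  if (!vi %in% nj) {
    stop(sprintf("'%s' is not adjacent to '%s'", vj, vi))
  }
  setdiff(nj, common_neighbors(g, vi, vj))
}

#' Influence contributed by a neighbor's exclusive neighborhood
#'
#' Sums \code{\link{gamma_term}} over the members of
#' \eqn{EN(v_i, v_j)} excluding the focal node \code{vi} itself (default).
#' With \code{include_focal = TRUE} the focal node's own term enters the
#' sum as well -- a sensitivity switch, off by default to match the
#' method's worked arithmetic.
#'
#' @param g an igraph graph.
#' @param vi a node identifier.
#' @param vj a neighbor of \code{vi}.
#' @param include_focal logical; include \code{vi}'s own term in the sum.
#' @return non-negative numeric.
#' @export
exclusive_influence <- function(g, vi, vj, include_focal = FALSE) {
  en <- exclusive_neighborhood(g, vi, vj)
  if (!include_focal) en <- setdiff(en, vi)
  if (length(en) == 0L) return(0)
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name
  ks <- kshell(g)
  sum(gamma_term(ks[en], deg[en], max_degree(g)))
}

#' Initial influence a neighbor provides
#'
#' \eqn{NI(v_j) = \Gamma(v_j) + I(v_j)}: the neighbor's own log-damped
#' term plus the contribution of its exclusive neighborhood.
#'
#' @param gamma non-negative numeric, the neighbor's own term.
#' @param excl non-negative numeric, the exclusive-neighborhood sum.
#' @return numeric.
#' @export
neighbor_initial_influence <- function(gamma, excl) {
  stopifnot(all(gamma >= 0), all(excl >= 0))
  gamma + excl
}

#' Relevance between two nodes
#'
#' The smoothed common-neighbor overlap
#' \eqn{H(v_i, v_j) = (|CN(v_i, v_j)| + 1) / nums}, where \code{nums} is
#' the total node count (isolated nodes included). The +1 keeps the weight
#' strictly positive when the two nodes share no neighbor.
#'
#' @param g a non-empty igraph graph.
#' @param vi,vj distinct node identifiers.
#' @return numeric in (0, 1] for any graph with enough nodes.
#' @examples
#' # two adjacent nodes sharing 2 common neighbors in a 23-node network:
#' # (2 + 1) / 23 = 0.1304 to 4 d.p.
#' @export
relevance <- function(g, vi, vj) {
  if (igraph::vcount(g) == 0L) stop("relevance is undefined on an empty graph")
  (length(common_neighbors(g, vi, vj)) + 1) / igraph::vcount(g)
}

#' Actual influence a neighbor provides
#'
#' \eqn{PNI(v_j) = NI(v_j) \cdot H(v_i, v_j)}: the initial influence
#' scaled down by the relevance weight, so neighbor contributions do not
#' swamp the node's own influence.
#'
#' @param ni non-negative numeric initial influence.
#' @param h relevance weight in (0, 1].
#' @return numeric.
#' @export
neighbor_actual_influence <- function(ni, h) {
  stopifnot(all(ni >= 0), all(h > 0), all(h <= 1))
  ni * h
}

# Shared internal engine: score one node given precomputed graph tables.
# adj: named list of neighbor-name vectors; gam: named gamma terms;
# si: named self-influences; nums: node count.
score_one <- function(vi, adj, gam, si, nums, include_focal) {
  nb <- adj[[vi]]
  if (length(nb) == 0L) {
    return(list(
      node = vi, si = si[[vi]],
      neighbors = data.frame(neighbor = character(0), gamma = numeric(0),
                             excl = numeric(0), ni = numeric(0),
                             h = numeric(0), pni = numeric(0),
                             stringsAsFactors = FALSE),
      k = 0
    ))
  }
  recs <- lapply(nb, function(vj) {
    nj <- adj[[vj]]
    cn <- intersect(adj[[vi]], nj)
    en <- setdiff(nj, cn)       # always contains vi
    terms <- if (include_focal) en else setdiff(en, vi)
    excl <- if (length(terms) == 0L) 0 else sum(gam[terms])
    gamma <- gam[[vj]]
    ni <- gamma + excl
    h <- (length(cn) + 1) / nums
    c(gamma = gamma, excl = excl, ni = ni, h = h, pni = ni * h)
  })
  mat <- do.call(rbind, recs)
  neighbors <- data.frame(neighbor = nb, mat,
                          stringsAsFactors = FALSE, row.names = NULL)
  list(node = vi, si = si[[vi]], neighbors = neighbors,
       k = si[[vi]] + sum(neighbors$pni))
}

precompute_tables <- function(g) {
  nms <- igraph::V(g)$name
  deg <- as.integer(igraph::degree(g))
  ks <- as.integer(kshell(g))
  names(deg) <- nms
  names(ks) <- nms
  kmax <- max(deg)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), function(v) nms[v])
  names(adj) <- nms
  gam <- rep(NA_real_, length(nms))
  names(gam) <- nms
  nonisolated <- deg >= 1L
  if (any(nonisolated)) {
    gam[nonisolated] <- gamma_term(ks[nonisolated], deg[nonisolated], kmax)
  }
  si <- as.numeric(ks + deg)
  names(si) <- nms
  list(nms = nms, deg = deg, ks = ks, kmax = kmax, adj = adj, gam = gam,
       si = si, nums = length(nms))
}

#' Score a single node, with the full audit breakdown
#'
#' Computes the node's overall influence
#' \eqn{K(v_i) = SI(v_i) + \sum_{v_j \in Nei(v_i)} PNI(v_j)} together with
#' every intermediate per-neighbor term. An isolated node scores 0.
#'
#' @param g a non-empty igraph graph.
#' @param vi a node identifier.
#' @param include_focal see \code{\link{exclusive_influence}}.
#' @return a list of class \code{"influence_breakdown"}: \code{node},
#'   \code{si}, a per-neighbor data frame (\code{neighbor}, \code{gamma},
#'   \code{excl}, \code{ni}, \code{h}, \code{pni}) and the final \code{k}.
#' @export
mnen_score <- function(g, vi, include_focal = FALSE) {
  if (igraph::vcount(g) == 0L) stop("cannot score a node of an empty graph")
  if (!vi %in% igraph::V(g)$name) stop(sprintf("unknown node: '%s'", vi))
  tb <- precompute_tables(g)
  out <- score_one(vi, tb$adj, tb$gam, tb$si, tb$nums, include_focal)
  names(out$si) <- NULL
  structure(out, class = "influence_breakdown")
}

#' @export
print.influence_breakdown <- function(x, ...) {
  cat(sprintf("Influence breakdown for node '%s'\n", x$node))
  cat(sprintf("  self-influence SI = %g\n", x$si))
  if (nrow(x$neighbors) > 0) {
    cat(sprintf("  neighbor contributions (sum PNI = %g):\n",
                sum(x$neighbors$pni)))
    print(x$neighbors, digits = 4, row.names = FALSE)
  } else {
    cat("  (isolated node, no neighbor contributions)\n")
  }
  cat(sprintf("  overall influence K = %g\n", x$k))
  invisible(x)
}

#' Fit MNEN influence scores for every node of a network
#'
#' The multi-order-neighbors / exclusive-neighborhood centrality: each
#' node's influence is its self-influence (degree + k-shell index) plus,
#' for every neighbor, that neighbor's log-damped k-shell term and the
#' terms of the neighbor's exclusive neighborhood, scaled by a
#' common-neighbor relevance weight. Parameter-free; the only switch is
#' whether the focal node's own term enters the exclusive-neighborhood
#' sum (off by default).
#'
#' @param g a non-empty igraph graph (undirected, simple). Isolated nodes
#'   are permitted and score 0.
#' @param include_focal see \code{\link{exclusive_influence}}.
#' @return an object of class \code{"mnen"} with components
#'   \code{scores} (named numeric K per node), \code{si}, \code{pni_sum},
#'   \code{breakdowns} (list of \code{\link{mnen_score}}-style records),
#'   \code{kmax}, \code{nums} and the matched \code{call}. Use
#'   \code{coef()} for the scores and \code{\link{ranking}} for the
#'   ordered table.
#' @examples
#' g <- toy_graph()
#' fit <- mnen(g)
#' coef(fit)["v4"] # 10.582 to 3 d.p.
#' @export
mnen <- function(g, include_focal = FALSE) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) == 0L) stop("cannot score an empty graph")
  tb <- precompute_tables(g)
  breakdowns <- lapply(tb$nms, score_one, adj = tb$adj, gam = tb$gam,
                       si = tb$si, nums = tb$nums,
                       include_focal = include_focal)
  names(breakdowns) <- tb$nms
  scores <- vapply(breakdowns, `[[`, 0, "k")
  si <- vapply(breakdowns, `[[`, 0, "si")
  structure(
    list(scores = scores, si = si, pni_sum = scores - si,
         breakdowns = breakdowns, kmax = tb$kmax, nums = tb$nums,
         include_focal = include_focal, call = match.call()),
    class = "mnen"
  )
}

#' @export
print.mnen <- function(x, ...) {
  cat("MNEN influence scores\n")
  cat(sprintf("  network: %d nodes, kmax = %d\n", x$nums, x$kmax))
  top <- utils::head(ranking(x), 5)
  cat("  top nodes:\n")
  print.data.frame(top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mnen <- function(object, ...) {
  rk <- ranking(object)
  rk$si <- object$si[rk$node]
  rk$pni_sum <- object$pni_sum[rk$node]
  structure(list(ranking = rk, nums = object$nums, kmax = object$kmax),
            class = "summary.mnen")
}

#' @export
print.summary.mnen <- function(x, ...) {
  cat(sprintf("MNEN scores for %d nodes (kmax = %d)\n", x$nums, x$kmax))
  print(x$ranking, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mnen <- function(object, ...) object$scores

#' @export
plot.mnen <- function(x, top = min(20L, x$nums), ...) {
  rk <- utils::head(ranking(x), top)
  graphics::barplot(rev(rk$score), names.arg = rev(rk$node), horiz = TRUE,
                    las = 1, xlab = "influence K", ...)
  invisible(x)
}

#' Ordered node ranking from a score set
#'
#' Generic. Nodes are ordered by descending score; ties break by ascending
#' node identifier (numerically when identifiers share a common
#' prefix-plus-integer form, else lexicographically).
#'
#' @param x an object carrying per-node scores.
#' @param ... passed to methods.
#' @return a data.frame of class \code{"node_ranking"} with columns
#'   \code{node}, \code{score}, \code{rank} and a \code{"method"} attribute.
#' @export
ranking <- function(x, ...) UseMethod("ranking")

#' @rdname ranking
#' @export
ranking.mnen <- function(x, ...) {
  make_ranking(x$scores, method = "mnen")
}

#' @rdname ranking
#' @param method label recorded on the result.
#' @export
ranking.numeric <- function(x, method = "scores", ...) {
  make_ranking(x, method = method)
}

make_ranking <- function(scores, method) {
  stopifnot(!is.null(names(scores)), !anyDuplicated(names(scores)))
  ord <- order(-scores, natural_order_key(names(scores)))
  out <- data.frame(node = names(scores)[ord],
                    score = unname(scores[ord]),
                    rank = seq_along(scores),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "method") <- method
  class(out) <- c("node_ranking", "data.frame")
  out
}

#' @export
print.node_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Node ranking (%s), %d nodes\n",
              attr(x, "method"), nrow(x)))
  print.data.frame(utils::head(x, n), digits = 4, row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Write a ranking (or MNEN fit) as a tab-separated table
#'
#' For a \code{\link{mnen}} fit the columns are node, K, SI, PNI_sum and
#' rank; for a plain ranking, node, score and rank. Metadata lines are
#' prefixed with \code{#}.
#'
#' @param x a \code{"mnen"} fit or \code{"node_ranking"} table.
#' @param path output file path.
#' @param header optional extra '#' metadata lines.
#' @return \code{path}, invisibly.
#' @export
write_ranking <- function(x, path, header = NULL) {
  if (inherits(x, "mnen")) {
    rk <- ranking(x)
    tab <- data.frame(node = rk$node, K = rk$score,
                      SI = unname(x$si[rk$node]),
                      PNI_sum = unname(x$pni_sum[rk$node]),
                      rank = rk$rank, stringsAsFactors = FALSE)
    meta <- "method: mnen"
  } else if (inherits(x, "node_ranking")) {
    tab <- as.data.frame(x)
    meta <- paste0("method: ", attr(x, "method"))
  } else {
    stop("write_ranking expects a 'mnen' fit or a 'node_ranking'")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c(meta, header)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
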