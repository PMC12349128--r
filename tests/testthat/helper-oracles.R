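# Independent brute-force oracles. These deliberately re-derive every
# quantity from raw adjacency with naive loops, sharing no code with the
# package internals they check.

# Naive repeated-scan k-core peeling.
oracle_kshell <- function(g) {
  nms <- igraph::V(g)$name
  ks <- stats::setNames(integer(length(nms)), nms)
  h <- g
  k <- 0L
  while (igraph::vcount(h) > 0L) {
    repeat {
      degs <- igraph::degree(h)
      victims <- igraph::V(h)$name[degs <= k]
      if (length(victims) == 0L) break
      ks[victims] <- k
      h <- igraph::delete_vertices(h, victims)
    }
    k <- k + 1L
  }
  ks
}

# Straight-line transcription of the influence formulas from the dense
# adjacency matrix, using oracle_kshell for shell indices.
oracle_mnen <- function(g, include_focal = FALSE) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  nms <- rownames(A)
  deg <- rowSums(A)
  ks <- oracle_kshell(g)[nms]
  kmax <- max(deg)
  n <- length(nms)
  K <- stats::setNames(numeric(n), nms)
  for (vi in nms) {
    si <- ks[[vi]] + deg[[vi]]
    total <- 0
    for (vj in nms[A[vi, ] == 1]) {
      gam <- ks[[vj]]^(log10(deg[[vj]]) / kmax)
      cn <- nms[A[vi, ] == 1 & A[vj, ] == 1]
      en <- setdiff(nms[A[vj, ] == 1], cn)
      terms <- if (include_focal) en else setdiff(en, vi)
      excl <- 0
      for (vr in terms) excl <- excl + ks[[vr]]^(log10(deg[[vr]]) / kmax)
      h <- (length(cn) + 1) / n
      total <- total + (gam + excl) * h
    }
    K[vi] <- si + total
  }
  K
}

# O(m^2) double loop over unordered pairs, three-way tie classification.
oracle_kendall <- function(a, b) {
  b <- b[names(a)]
  m <- length(a)
  mc <- 0L
  md <- 0L
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) {
      s <- (a[[i]] - a[[j]]) * (b[[i]] - b[[j]])
      if (s > 0) mc <- mc + 1L else if (s < 0) md <- md + 1L
    }
  }
  2 * (mc - md) / (m * (m - 1))
}

# Hand-written BFS distance vector from one source over an adjacency list.
oracle_bfs <- function(adj, src) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

oracle_closeness <- function(g) {
  nms <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  s <- vapply(seq_along(nms), function(v) {
    d <- oracle_bfs(adj, v)
    d <- d[-v]
    finite <- is.finite(d)
    if (!any(finite)) 0 else sum(finite) / sum(d[finite])
  }, 0)
  stats::setNames(s, nms)
}

# Exact outcome-tree enumeration of the discrete-time SIR final size for
# beta = 1 on a tiny graph: returns the exact mean and variance of
# |ever infected|. Recovery is deterministic, so a state is just the
# (frozen, infectious, susceptible) partition; infections of the current
# candidates are enumerated as independent Bernoulli outcomes.
oracle_sir_exact <- function(g, seeds, alpha) {
  nms <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  n <- length(adj)
  ex <- 0
  ex2 <- 0
  recurse <- function(status, prob) {
    inf <- which(status == 1L)
    if (length(inf) == 0L) {
      size <- sum(status == 2L)
      ex <<- ex + prob * size
      ex2 <<- ex2 + prob * size^2
      return(invisible(NULL))
    }
    cand <- unique(unlist(adj[inf]))
    cand <- cand[status[cand] == 0L]
    base <- status
    base[inf] <- 2L
    if (length(cand) == 0L) {
      recurse(base, prob)
      return(invisible(NULL))
    }
    k <- vapply(cand, function(cc) sum(status[adj[[cc]]] == 1L), 0L)
    p <- 1 - (1 - alpha)^k
    for (mask in 0:(2^length(cand) - 1)) {
      hit <- as.logical(bitwAnd(mask, 2^(seq_along(cand) - 1)))
      pr <- prod(ifelse(hit, p, 1 - p))
      if (pr == 0) next
      st <- base
      st[cand[hit]] <- 1L
      recurse(st, prob * pr)
    }
    invisible(NULL)
  }
  status0 <- integer(n)
  status0[match(seeds, nms)] <- 1L
  recurse(status0, 1)
  list(mean = ex, var = ex2 - ex^2)
}

# Seeded Erdos-Renyi test graph with named vertices; may be disconnected.
random_test_graph <- function(n, p, seed) {
  g <- mnen::generate_graph("random", n = n, p = p, seed = seed)
  g
}
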