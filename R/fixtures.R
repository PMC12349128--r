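#' Seeded synthetic network generators
#'
#' Simple undirected test networks from four standard families:
#' \describe{
#'   \item{random}{Erdos-Renyi G(n, p).}
#'   \item{scale_free}{Barabasi-Albert preferential attachment, `m` edges
#'     added per new node.}
#'   \item{small_world}{Watts-Strogatz ring lattice (each node tied to
#'     `k` nearest neighbors) with rewiring probability `rewire_p`.}
#'   \item{core_periphery}{a clique of `core_size` nodes, each with
#'     `leaves_per_core` pendant leaves.}
#' }
#' Output is always simple (loops and multi-edges removed), vertices named
#' \code{v1..vn}, and bit-reproducible for a fixed seed.
#'
#' @param model one of \code{"random"}, \code{"scale_free"},
#'   \code{"small_world"}, \code{"core_periphery"}.
#' @param n number of nodes (random / scale_free / small_world).
#' @param p edge probability for \code{"random"}, in [0, 1].
#' @param m attachment edges per node for \code{"scale_free"}.
#' @param k nearest-neighbor count (even) for \code{"small_world"}.
#' @param rewire_p rewiring probability for \code{"small_world"}.
#' @param core_size,leaves_per_core sizes for \code{"core_periphery"}.
#' @param seed integer RNG seed.
#' @return an undirected simple igraph graph with named vertices.
#' @export
generate_graph <- function(model = c("random", "scale_free", "small_world",
                                     "core_periphery"),
                           n = 100L, p = 0.05, m = 2L, k = 4L,
                           rewire_p = 0.1, core_size = 5L,
                           leaves_per_core = 4L, seed = 1L) {
  model <- match.arg(model)
  g <- switch(
    model,
    random = {
      stopifnot(n >= 1, p >= 0, p <= 1)
      with_seed(seed, igraph::sample_gnp(n, p))
    },
    scale_free = {
      stopifnot(n >= 2, m >= 1)
      with_seed(seed, igraph::sample_pa(n, m = m, directed = FALSE))
    },
    small_world = {
      stopifnot(n >= 3, k >= 2, k %% 2 == 0, rewire_p >= 0, rewire_p <= 1)
      with_seed(seed,
                igraph::sample_smallworld(1, n, k / 2, rewire_p))
    },
    core_periphery = {
      stopifnot(core_size >= 2, leaves_per_core >= 0)
      core <- igraph::make_full_graph(core_size)
      total <- core_size * (1 + leaves_per_core)
      g0 <- igraph::add_vertices(core, total - core_size)
      if (leaves_per_core > 0) {
        leaf <- core_size
        extra <- integer(0)
        for (c_i in seq_len(core_size)) {
          for (l in seq_len(leaves_per_core)) {
            leaf <- leaf + 1L
            extra <- c(extra, c_i, leaf)
          }
        }
        g0 <- igraph::add_edges(g0, extra)
      }
      g0
    }
  )
  g <- igraph::simplify(g)
  igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  g
}

#' The 23-node worked-example network
#'
#' A fixed toy network consistent with every published local constraint of
#' the method's worked example: node v4 has neighbors
#' \{v1, v2, v3, v5, v11, v12\}, v3 has \{v1, v2, v4, v9, v10\}, v5 has
#' \{v2, v4, v14\}; Ks(v4) = Ks(v3) = 3; the maximum degree is 6; 23 nodes
#' in total. The remainder of the topology is a frozen synthetic
#' completion (see the comments in the shipped edge-list file); global
#' quantities that depend on it are deliberately never asserted.
#'
#' @return an igraph graph with 23 named vertices.
#' @export
toy_graph <- function() {
  path <- system.file("extdata", "toy_network.tsv", package = "mnen")
  if (!nzchar(path)) stop("toy network fixture not found")
  read_edgelist(path)
}
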